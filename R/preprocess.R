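#' Binarize symptom and index records
#'
#' Collapses raw clinical records to 0/1 bits using the study coding:
#' \itemize{
#'   \item TCM symptoms scored none/mild/severe (0/1/2): positive (score >= 1)
#'     becomes 1, "mild" counts as positive;
#'   \item qualitative Western indexes: `-` (negative) becomes 0, weak or
#'     strong positive (`+`, `++`, `+++`) becomes 1;
#'   \item quantitative Western indexes: values inside the normal range
#'     `[low, high]` become 0, values above or below it become 1.
#' }
#' Missing values are treated as absent/negative (0); a warning reports how
#' many were imputed.  Already-binary input is returned unchanged
#' (binarization is idempotent).
#'
#' @param value raw values: numeric scores for `tcm_symptom` and
#'   `quantitative_index`, character tokens for `qualitative_index`.
#' @param kind one of `"tcm_symptom"`, `"qualitative_index"`,
#'   `"quantitative_index"`; recycled to the length of `value`.
#' @param low,high normal-range bounds, required (finite, `low <= high`) for
#'   quantitative records; recycled.
#' @return integer vector of 0/1 bits.
#' @export
binarize <- function(value, kind, low = NA_real_, high = NA_real_) {
  kinds <- c("tcm_symptom", "qualitative_index", "quantitative_index")
  kind <- rep_len(as.character(kind), length(value))
  if (!all(kind %in% kinds)) {
    stop("unknown record kind: ", paste(setdiff(kind, kinds), collapse = ", "))
  }
  low <- rep_len(low, length(value))
  high <- rep_len(high, length(value))
  out <- integer(length(value))
  n_missing <- 0L

  tcm <- kind == "tcm_symptom"
  if (any(tcm)) {
    v <- suppressWarnings(as.numeric(value[tcm]))
    n_missing <- n_missing + sum(is.na(v))
    out[tcm] <- as.integer(!is.na(v) & v >= 1)
  }
  ql <- kind == "qualitative_index"
  if (any(ql)) {
    v <- trimws(as.character(value[ql]))
    v[v == "−"] <- "-"                 # unicode minus
    neg <- v %in% c("-", "0", "neg", "negative")
    pos <- v %in% c("+", "++", "+++", "1", "pos", "positive")
    miss <- is.na(value[ql]) | v == ""
    bad <- !(neg | pos | miss)
    if (any(bad)) {
      stop("unknown qualitative token(s): ",
           paste(unique(v[bad]), collapse = ", "))
    }
    n_missing <- n_missing + sum(miss)
    out[ql] <- as.integer(pos & !miss)
  }
  qt <- kind == "quantitative_index"
  if (any(qt)) {
    lo <- as.numeric(low[qt]); hi <- as.numeric(high[qt])
    if (any(!is.finite(lo)) || any(!is.finite(hi))) {
      stop("quantitative records require a finite normal range (low, high)")
    }
    if (any(lo > hi)) stop("normal range must satisfy low <= high")
    v <- suppressWarnings(as.numeric(value[qt]))
    n_missing <- n_missing + sum(is.na(v))
    out[qt] <- as.integer(!is.na(v) & (v < lo | v > hi))
  }
  if (n_missing > 0L) {
    warning(sprintf("%d missing value(s) treated as negative (0)", n_missing))
  }
  out
}

#' Assign subjects to study groups
#'
#' Grouping rule of the study design:
#' \itemize{
#'   \item diagnosed disease + fatigue symptom: disease fatigue group;
#'   \item no positive Western indexes + fatigue + H20 score 60-79:
#'     sub-health fatigue group;
#'   \item no positive Western indexes + no fatigue + H20 score 80-100:
#'     healthy controls;
#'   \item anything else: unclassified (excluded from analysis).
#' }
#' "No positive indexes" is operationalized as all binarized Western indexes
#' equal to 0, passed through `positive_index`.
#'
#' @param h20 health questionnaire score(s) in `[0, 100]`.
#' @param fatigue logical: fatigue symptom present.
#' @param disease logical: clinician-diagnosed disease present.
#' @param positive_index logical: any positive (binarized = 1) Western index;
#'   defaults to `disease`.
#' @return factor with levels `healthy`, `subhealth_fatigue`,
#'   `disease_fatigue`, `unclassified`.
#' @export
assign_group <- function(h20, fatigue, disease,
                         positive_index = disease) {
  if (any(!is.finite(h20)) || any(h20 < 0) || any(h20 > 100)) {
    stop("h20 scores must lie in [0, 100]")
  }
  n <- length(h20)
  fatigue <- rep_len(as.logical(fatigue), n)
  disease <- rep_len(as.logical(disease), n)
  positive_index <- rep_len(as.logical(positive_index), n)
  out <- rep("unclassified", n)
  out[!positive_index & !fatigue & h20 >= 80 & h20 <= 100] <- "healthy"
  out[!positive_index & fatigue & h20 >= 60 & h20 <= 79] <- "subhealth_fatigue"
  out[disease & fatigue] <- "disease_fatigue"
  factor(out, levels = c("healthy", "subhealth_fatigue", "disease_fatigue",
                         "unclassified"))
}

#' Exclude subjects with outlying tongue/pulse values
#'
#' Tukey-fence screening on every numeric variable: with lower and upper
#' hinges Q1, Q3 (Tukey's hinges, as in [stats::fivenum()]) and
#' IQR = Q3 - Q1, a value beyond `Q1 - fence_inner * IQR` or
#' `Q3 + fence_inner * IQR` flags the subject as an outlier; beyond the outer
#' fence (`fence_outer`, default 3) it is logged as extreme.  Subjects flagged
#' at or beyond the chosen fence (`drop = "inner"` by default, so outliers AND
#' extremes) are removed.  Variables with zero IQR are skipped and logged.
#'
#' @param table data.frame with an id column and numeric variables.
#' @param fence_inner,fence_outer positive fence multipliers (may be `Inf`).
#' @param drop drop subjects beyond the `"inner"` (default) or only beyond
#'   the `"outer"` fence.
#' @param id_col name of the subject id column (default `"id"`).
#' @param vars variables to screen; default all numeric columns except id.
#' @return list with `table` (retained rows), `log` (data.frame `id`,
#'   `variable`, `value`, `severity`), `skipped` (zero-IQR variables),
#'   `n_dropped`.
#' @export
exclude_outlier_subjects <- function(table, fence_inner = 1.5,
                                     fence_outer = 3,
                                     drop = c("inner", "outer"),
                                     id_col = "id", vars = NULL) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (fence_inner <= 0 || fence_outer <= 0) stop("fences must be positive")
  if (fence_outer < fence_inner) stop("outer fence must be >= inner fence")
  drop <- match.arg(drop)
  if (is.null(vars)) {
    vars <- names(table)[vapply(table, is.numeric, logical(1L))]
    vars <- setdiff(vars, id_col)
  }
  ids <- if (id_col %in% names(table)) as.character(table[[id_col]]) else
    as.character(seq_len(nrow(table)))

  log_rows <- list()
  skipped <- character()
  flag_inner <- rep(FALSE, nrow(table))
  flag_outer <- rep(FALSE, nrow(table))
  for (v in vars) {
    x <- table[[v]]
    fn <- stats::fivenum(x, na.rm = TRUE)
    q1 <- fn[2L]; q3 <- fn[4L]
    iqr <- q3 - q1
    if (!is.finite(iqr) || iqr == 0) {
      skipped <- c(skipped, v)
      next
    }
    out_in <- !is.na(x) & (x < q1 - fence_inner * iqr |
                             x > q3 + fence_inner * iqr)
    out_ex <- !is.na(x) & (x < q1 - fence_outer * iqr |
                             x > q3 + fence_outer * iqr)
    flag_inner <- flag_inner | out_in
    flag_outer <- flag_outer | out_ex
    if (any(out_in)) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(id = ids[out_in], variable = v, value = x[out_in],
                   severity = ifelse(out_ex[out_in], "extreme", "outlier"))
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(id = character(), variable = character(), value = numeric(),
               severity = character())
  rownames(log) <- NULL
  dropped <- if (drop == "inner") flag_inner else flag_outer
  out <- table[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("tongue_vars", "pulse_vars")) {
    if (!is.null(attr(table, a))) attr(out, a) <- attr(table, a)
  }
  list(table = out, log = log, skipped = skipped,
       n_dropped = sum(dropped))
}
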