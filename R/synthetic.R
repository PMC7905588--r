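#' Default symptom / index feature catalog
#'
#' A compact catalog of TCM symptom codes (tongue coating, pulse quality,
#' emotional/sleep, head-eye, body-feeling items) and Western medicine index
#' codes (blood routine, blood pressure, urine routine, metabolic items) with
#' baseline population prevalences.  Codes follow the field's shorthand
#' (TC = tongue coating, PU = pulse, EM = emotion/sleep, HE = head/eye,
#' LP = pain, QP = body feeling, THA = chest/abdomen; BRT = blood routine,
#' RUT = urine routine, BI = biochemistry).
#'
#' @return data.frame with columns `code`, `label`, `block`, `prevalence`.
#' @export
default_feature_catalog <- function() {
  sym <- rbind(
    c("TC1",  "white tongue coating",   0.10),
    c("TC2",  "yellow tongue coating",  0.08),
    c("TC6",  "thick coating",          0.07),
    c("TC11", "greasy coating",         0.06),
    c("LP1",  "headache",               0.06),
    c("QP1",  "sour",                   0.07),
    c("EM3",  "irritability",           0.08),
    c("EM6",  "insomnia",               0.08),
    c("EM7",  "dreaminess",             0.09),
    c("HE1",  "dizziness",              0.05),
    c("HE13", "xerophthalmia",          0.05),
    c("THA4", "chest distress",         0.05),
    c("PU15", "wiry pulse",             0.06),
    c("QP3",  "limb heaviness",         0.04),
    c("EM1",  "listlessness",           0.06),
    c("TB3",  "pale tongue",            0.05),
    c("TB5",  "red tongue",             0.05),
    c("HE5",  "tinnitus",               0.03),
    c("LP4",  "lumbar soreness",        0.05),
    c("THA1", "palpitation",            0.04))
  idx <- rbind(
    c("BRT8",  "hemoglobin",                  0.04),
    c("BRT10", "hematocrit",                  0.04),
    c("BRT12", "percentage of monocyte",      0.05),
    c("BRT13", "basophil",                    0.05),
    c("BRT20", "platelet distribution width", 0.05),
    c("SBP",   "systolic blood pressure",     0.06),
    c("DBP",   "diastolic blood pressure",    0.05),
    c("RUT5",  "pH of urine",                 0.04),
    c("BI15",  "uric acid",                   0.05),
    c("BMI",   "body mass index",             0.06),
    c("BI2",   "fasting glucose",             0.04),
    c("BI7",   "triglycerides",               0.05),
    c("BI9",   "ALT",                         0.04),
    c("US1",   "fatty liver on ultrasound",   0.04),
    c("BRT1",  "white blood cell count",      0.03))
  out <- data.frame(code = c(sym[, 1L], idx[, 1L]),
                    label = c(sym[, 2L], idx[, 2L]),
                    block = rep(c("symptom", "index"),
                                c(nrow(sym), nrow(idx))),
                    prevalence = as.numeric(c(sym[, 3L], idx[, 3L])))
  out
}

#' Default latent co-occurrence factors
#'
#' Latent binary factors that drive symptom/index co-occurrence.  Each factor
#' carries loadings on a subset of features and a per-group activation
#' probability; an active factor raises the feature probabilities via a
#' noisy-OR rule (see [gen_binary_cohort()]).  Activation probabilities are
#' low in healthy controls, high for symptom factors in the sub-health
#' fatigue group, and high for both symptom and index factors in the disease
#' fatigue group, mimicking how clinical abnormality clusters differ between
#' the study groups.
#'
#' @return list of factors, each `list(loadings = named numeric, activation =
#'   c(healthy, subhealth, disease))`.
#' @export
default_latent_factors <- function() {
  f <- function(loadings, activation) list(loadings = loadings,
                                           activation = activation)
  list(
    coating = f(c(TC1 = 0.55, TC2 = 0.40, TC6 = 0.45, TC11 = 0.35, QP1 = 0.40),
                c(healthy = 0.08, subhealth = 0.55, disease = 0.60)),
    neuro = f(c(EM3 = 0.45, EM6 = 0.45, EM7 = 0.50, LP1 = 0.45, HE1 = 0.35,
                EM1 = 0.35),
              c(healthy = 0.06, subhealth = 0.50, disease = 0.45)),
    somatic = f(c(QP1 = 0.30, THA4 = 0.35, HE13 = 0.35, PU15 = 0.30,
                  LP4 = 0.25, QP3 = 0.25),
                c(healthy = 0.05, subhealth = 0.40, disease = 0.40)),
    metabolic = f(c(SBP = 0.55, DBP = 0.45, BMI = 0.40, BI15 = 0.35,
                    BI2 = 0.30, BI7 = 0.35, US1 = 0.30, TC11 = 0.15),
                  c(healthy = 0.02, subhealth = 0.03, disease = 0.55)),
    hematologic = f(c(BRT8 = 0.35, BRT10 = 0.35, BRT12 = 0.40, BRT13 = 0.45,
                      BRT20 = 0.45, RUT5 = 0.30, BRT1 = 0.25, TC1 = 0.15),
                    c(healthy = 0.02, subhealth = 0.03, disease = 0.50)))
}

default_h20_params <- function() {
  list(healthy = list(mean = 88, sd = 5, lower = 80, upper = 100),
       subhealth = list(mean = 70, sd = 4, lower = 60, upper = 79),
       disease = list(mean = 62, sd = 10, lower = 0, upper = 100))
}

#' Specification of a synthetic study cohort
#'
#' Defaults mirror the structure of the study population: 742 healthy
#' controls, 361 sub-health fatigue subjects, 1529 disease fatigue subjects;
#' health questionnaire (H20) scores truncated to each group's defining
#' interval (80-100 healthy, 60-79 sub-health); symptom/index co-occurrence
#' driven by latent factors.
#'
#' @param n_healthy,n_subhealth,n_disease group sizes (>= 0).
#' @param feature_catalog data.frame `code`, `label`, `block`, `prevalence`.
#' @param latent_factors list as in [default_latent_factors()]; loadings and
#'   activation probabilities must lie in `[0, 1]`.
#' @param h20_params per-group list `mean`, `sd`, `lower`, `upper` for the
#'   truncated-normal H20 score distribution.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 742L, n_subhealth = 361L,
                        n_disease = 1529L,
                        feature_catalog = default_feature_catalog(),
                        latent_factors = default_latent_factors(),
                        h20_params = default_h20_params(),
                        seed = 1L) {
  ns <- c(n_healthy, n_subhealth, n_disease)
  if (any(ns < 0) || any(ns != round(ns))) stop("group sizes must be non-negative integers")
  feature_catalog <- as.data.frame(feature_catalog)
  stopifnot(all(c("code", "block", "prevalence") %in% names(feature_catalog)))
  if (is.null(feature_catalog$label)) feature_catalog$label <- feature_catalog$code
  pv <- feature_catalog$prevalence
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1)) {
    stop("feature prevalences must lie in [0, 1]")
  }
  if (!all(feature_catalog$block %in% c("symptom", "index"))) {
    stop("feature block must be 'symptom' or 'index'")
  }
  for (f in latent_factors) {
    if (any(f$loadings < 0) || any(f$loadings > 1)) {
      stop("factor loadings must lie in [0, 1]")
    }
    if (any(f$activation < 0) || any(f$activation > 1)) {
      stop("factor activation probabilities must lie in [0, 1]")
    }
    if (!all(names(f$loadings) %in% feature_catalog$code)) {
      stop("factor loads on unknown feature(s): ",
           paste(setdiff(names(f$loadings), feature_catalog$code),
                 collapse = ", "))
    }
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_subhealth = as.integer(n_subhealth),
                 n_disease = as.integer(n_disease),
                 feature_catalog = feature_catalog,
                 latent_factors = latent_factors,
                 h20_params = h20_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated normal via inverse CDF (deterministic for a given RNG state)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic binary cohort
#'
#' Each subject activates each latent factor independently with the group's
#' activation probability; given the active set A, feature j is present with
#' probability
#' \deqn{p_j = 1 - (1 - \pi_j) \prod_{f \in A} (1 - \lambda_{fj})}
#' (noisy-OR mixing of the baseline prevalence \eqn{\pi_j} with the factor
#' loadings \eqn{\lambda_{fj}}), which guarantees valid probabilities and
#' co-occurrence that is monotone in the loadings.  H20 scores are drawn from
#' the group's truncated normal; fatigue is present in the sub-health and
#' disease groups, absent in healthy controls; disease subjects carry a
#' diagnosis subgroup label (hypertension / diabetes / hyperlipemia / fatty
#' liver, in the proportions of the study population).
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort`: `mat` (subjects x features 0/1 integer
#'   matrix), `subjects` (data.frame `id`, `group`, `subgroup`, `h20`,
#'   `fatigue`, `disease`), `features` (the catalog).
#' @export
gen_binary_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- c("healthy", "subhealth", "disease")
  ns <- c(spec$n_healthy, spec$n_subhealth, spec$n_disease)
  n <- sum(ns)
  group <- rep(groups, ns)
  cat_ <- spec$feature_catalog
  p <- nrow(cat_)

  # factor activations: n x F
  fac <- spec$latent_factors
  nf <- length(fac)
  act_prob <- vapply(fac, function(f) unname(f$activation[group]),
                     numeric(n))
  act_prob <- matrix(act_prob, nrow = n)
  A <- matrix(stats::rbinom(n * nf, 1L, as.vector(act_prob)), nrow = n)

  # log(1 - loading) matrix: F x p (0 where factor does not load)
  L <- matrix(0, nrow = nf, ncol = p,
              dimnames = list(names(fac), cat_$code))
  for (k in seq_len(nf)) {
    L[k, names(fac[[k]]$loadings)] <- log1p(-unname(fac[[k]]$loadings))
  }
  # 1 - p_ij = (1 - baseline_j) * exp(sum over active factors of log(1 - lambda))
  logq <- A %*% L
  one_minus <- matrix(rep(1 - cat_$prevalence, each = n), nrow = n) * exp(logq)
  prob <- 1 - one_minus

  mat <- matrix(stats::rbinom(n * p, 1L, as.vector(prob)), nrow = n,
                dimnames = list(sprintf("S%05d", seq_len(n)), cat_$code))
  storage.mode(mat) <- "integer"

  h20 <- numeric(n)
  for (g in groups) {
    hp <- spec$h20_params[[g]]
    idx <- group == g
    h20[idx] <- rtrunc_norm(sum(idx), hp$mean, hp$sd, hp$lower, hp$upper)
  }
  subgroup <- rep(NA_character_, n)
  dis <- group == "disease"
  if (any(dis)) {
    subgroup[dis] <- sample(c("hypertension", "diabetes", "hyperlipemia",
                              "fatty liver"),
                            sum(dis), replace = TRUE,
                            prob = c(311, 157, 518, 442))
  }
  subjects <- data.frame(id = rownames(mat),
                         group = group,
                         subgroup = subgroup,
                         h20 = round(h20, 1),
                         fatigue = group != "healthy",
                         disease = dis)
  structure(list(mat = mat, subjects = subjects, features = cat_),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d features (%s)\n",
              nrow(x$mat), ncol(x$mat),
              paste(sprintf("%s: %d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", ")))
  invisible(x)
}

default_tongue_loading <- function() {
  v <- c("TB-R" = 0.30, "TB-G" = 0.15, "TB-B" = 0.20, "TB-H" = 0.35,
         "TB-S" = 0.15, "TB-L" = 0.20, "TB-b" = 0.35, "TB-Cr" = 0.30,
         "TB-Cb" = -0.35, "TC-Cr" = 0.30, "TC-Cb" = -0.25, "TC-b" = 0.20,
         "perAll" = -0.30, "perPart" = -0.15)
  v / sqrt(sum(v^2))
}

default_pulse_loading <- function() {
  v <- c(h1 = 0.45, h3 = 0.35, h4 = -0.40, h5 = 0.20, t1 = -0.30,
         t4 = 0.15, t5 = 0.15, t = 0.20, w1 = 0.25, w2 = -0.30)
  v / sqrt(sum(v^2))
}

# physiologic-looking location/scale for each generated parameter
tongue_scales <- function(nm) {
  mu <- c("TB-R" = 150, "TB-G" = 90, "TB-B" = 95, "TB-H" = 12, "TB-S" = 0.40,
          "TB-L" = 55, "TB-b" = 14, "TB-Cr" = 155, "TB-Cb" = 110,
          "TC-Cr" = 145, "TC-Cb" = 118, "TC-b" = 12,
          "perAll" = 0.45, "perPart" = 0.80)
  sc <- mu * 0.06 + 0.5
  out <- list(mu = mu[nm], sc = sc[nm])
  out$mu[is.na(out$mu)] <- 0   # unknown parameter names: latent scale
  out$sc[is.na(out$sc)] <- 1
  out
}

pulse_scales <- function(nm) {
  mu <- c(h1 = 14, h3 = 7, h4 = 5, h5 = 1.5, t1 = 0.14, t4 = 0.36,
          t5 = 0.44, t = 0.85, w1 = 0.18, w2 = 0.24)
  sc <- mu * 0.08
  out <- list(mu = mu[nm], sc = sc[nm])
  out$mu[is.na(out$mu)] <- 0
  out$sc[is.na(out$sc)] <- 1
  out
}

#' Specification of a synthetic tongue-pulse table
#'
#' Defines a planted first canonical correlation `rho` between the tongue
#' colour block and the pulse sphygmogram block: a latent standard-normal
#' pair (u, v) with correlation `rho` drives the two blocks through unit-norm
#' loading vectors, plus independent per-variable Gaussian noise.  The default
#' `noise_sd = 0.12` keeps the population first canonical correlation within
#' 0.02 of the planted value (attenuation \eqn{\rho (1 - 1/(1 + \sigma^2))}).
#'
#' @param n_subjects number of subjects.
#' @param rho planted first canonical correlation, in `[0, 1]`. Default 0.42,
#'   a disease-fatigue-sized effect.
#' @param tongue_loading,pulse_loading unit-norm named loading vectors over
#'   the tongue colour parameters and the pulse base parameters.
#' @param noise_sd residual standard deviation per variable (latent scale).
#' @param seed integer seed.
#' @return list of class `tongue_pulse_spec`.
#' @export
tongue_pulse_spec <- function(n_subjects = 1160L, rho = 0.42,
                              tongue_loading = default_tongue_loading(),
                              pulse_loading = default_pulse_loading(),
                              noise_sd = 0.12, seed = 1L) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    stop("rho must lie in [0, 1]")
  }
  stopifnot(n_subjects >= 1, noise_sd >= 0)
  for (v in list(tongue_loading, pulse_loading)) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8) stop("loading vectors must have unit Euclidean norm")
    if (is.null(names(v))) stop("loading vectors must be named")
  }
  structure(list(n_subjects = as.integer(n_subjects), rho = rho,
                 tongue_loading = tongue_loading,
                 pulse_loading = pulse_loading,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tongue_pulse_spec")
}

#' Generate a synthetic tongue-pulse table
#'
#' Draws the latent correlated pair, builds each block as
#' `location + scale * (loading * latent + noise)` on physiologic-looking
#' positive scales, and appends the derived pulse ratio parameters
#' `h4_h1` (= h4/h1), `h3_h1`, `w2_t`, `h1_t1` computed from the generated
#' base parameters (ratio columns enter downstream CCA as ordinary columns).
#'
#' @param spec a [tongue_pulse_spec()].
#' @return data.frame of class `tongue_pulse`: `id`, tongue columns, pulse
#'   base columns, derived ratio columns.  Attributes `tongue_vars` and
#'   `pulse_vars` name the two blocks.
#' @export
gen_tongue_pulse <- function(spec) {
  stopifnot(inherits(spec, "tongue_pulse_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  u <- stats::rnorm(n)
  v <- spec$rho * u + sqrt(1 - spec$rho^2) * stats::rnorm(n)

  tl <- spec$tongue_loading
  pl <- spec$pulse_loading
  ts <- tongue_scales(names(tl))
  ps <- pulse_scales(names(pl))

  tongue <- sapply(seq_along(tl), function(j) {
    ts$mu[j] + ts$sc[j] * (tl[j] * u + spec$noise_sd * stats::rnorm(n))
  })
  colnames(tongue) <- names(tl)
  pulse <- sapply(seq_along(pl), function(j) {
    ps$mu[j] + ps$sc[j] * (pl[j] * v + spec$noise_sd * stats::rnorm(n))
  })
  colnames(pulse) <- names(pl)

  ratio_base <- c("h4", "h1", "h3", "w2", "t", "t1")
  if (all(ratio_base %in% colnames(pulse))) {
    ratios <- cbind(h4_h1 = pulse[, "h4"] / pulse[, "h1"],
                    h3_h1 = pulse[, "h3"] / pulse[, "h1"],
                    w2_t = pulse[, "w2"] / pulse[, "t"],
                    h1_t1 = pulse[, "h1"] / pulse[, "t1"])
  } else {
    ratios <- matrix(numeric(0), nrow = n, ncol = 0)
  }

  out <- data.frame(id = sprintf("S%05d", seq_len(n)), tongue, pulse, ratios,
                    check.names = FALSE)
  attr(out, "tongue_vars") <- names(tl)
  attr(out, "pulse_vars") <- c(names(pl), colnames(ratios))
  class(out) <- c("tongue_pulse", "data.frame")
  out
}

#' Split a tongue-pulse table into its two blocks
#'
#' @param table a `tongue_pulse` data.frame (or any data.frame plus explicit
#'   variable names).
#' @param tongue_vars,pulse_vars column names of each block; default taken
#'   from the table's attributes.
#' @return list with matrices `tongue` and `pulse`.
#' @export
tongue_pulse_blocks <- function(table,
                                tongue_vars = attr(table, "tongue_vars"),
                                pulse_vars = attr(table, "pulse_vars")) {
  stopifnot(!is.null(tongue_vars), !is.null(pulse_vars))
  list(tongue = as.matrix(table[, tongue_vars, drop = FALSE]),
       pulse = as.matrix(table[, pulse_vars, drop = FALSE]))
}

#' Write / read cohort and tongue-pulse CSV files
#'
#' `write_cohort()` writes one row per subject: `id`, `group`, `subgroup`,
#' `h20`, `fatigue`, `disease`, then the 0/1 feature columns.
#' `read_cohort()` reads such a file back; feature metadata (label, block) is
#' supplied through `catalog` (defaults to the package catalog, matched by
#' code; unmatched columns get block `NA`).
#'
#' @param cohort a `cohort` object.
#' @param path CSV path.
#' @param catalog feature metadata data.frame.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a `cohort` object.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cbind(cohort$subjects, as.data.frame(cohort$mat))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, catalog = default_feature_catalog()) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("id", "group", "subgroup", "h20", "fatigue", "disease")
  stopifnot(all(meta_cols %in% names(df)))
  feat_cols <- setdiff(names(df), meta_cols)
  mat <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$id
  idx <- match(feat_cols, catalog$code)
  features <- data.frame(code = feat_cols,
                         label = ifelse(is.na(idx), feat_cols,
                                        catalog$label[idx]),
                         block = ifelse(is.na(idx), NA_character_,
                                        catalog$block[idx]),
                         prevalence = ifelse(is.na(idx), NA_real_,
                                             catalog$prevalence[idx]))
  structure(list(mat = mat, subjects = df[, meta_cols], features = features),
            class = "cohort")
}

#' @rdname write_cohort
#' @param table a `tongue_pulse` data.frame.
#' @export
write_tongue_pulse <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param tongue_vars,pulse_vars block column names (defaults: the package's
#'   standard tongue and pulse parameter sets).
#' @export
read_tongue_pulse <- function(path,
                              tongue_vars = names(default_tongue_loading()),
                              pulse_vars = c(names(default_pulse_loading()),
                                             "h4_h1", "h3_h1", "w2_t",
                                             "h1_t1")) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c(tongue_vars, pulse_vars) %in% names(df)))
  attr(df, "tongue_vars") <- tongue_vars
  attr(df, "pulse_vars") <- pulse_vars
  class(df) <- c("tongue_pulse", "data.frame")
  df
}
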