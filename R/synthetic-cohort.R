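# Synthetic RCT cohorts with known ground truth. The generator emulates the
# trial design the pipeline targets: a two-arm (placebo pill vs no
# treatment) 8-week, six-visit design with twice-daily app VAS ratings over
# baseline (BL, 14 d), treatment 1 (T1, 14 d), washout 1 (W1, 7 d),
# treatment 2 (T2, 14 d) and washout 2 (W2, 7 d); questionnaire subscales
# with planted correlations to the magnitude of response; per-visit
# connectivity matrices with planted group-dependent edges; and subcortical
# volumes with planted rightward asymmetry in responders.

PERIOD_DAYS <- c(BL = 14L, T1 = 14L, W1 = 7L, T2 = 14L, W2 = 7L)
SCAN_VISITS <- c("V2", "V3", "V4", "V5")

#' Parameters of a synthetic cohort
#'
#' Defaults encode the study conditions of the emulated trial: 43 subjects
#' in the placebo arm and 20 in the no-treatment arm, responder fractions
#' 24/43 and 4/20, baseline phone rating 6.10 (SD 1.33) VAS units, 33%
#' analgesia at plateau with onset one day after treatment start, full
#' analgesia retention during washout, 38 questionnaire subscales, and a
#' 122-node connectivity scheme.
#'
#' @param n_ptx,n_notx arm sizes.
#' @param responder_fraction_ptx,responder_fraction_notx responder
#'   proportions per arm.
#' @param baseline_mean,baseline_sd between-subject distribution of the
#'   baseline pain level (VAS units).
#' @param analgesia_pct mean percent reduction at plateau for responders.
#' @param analgesia_pct_sd between-subject SD of the planted %analgesia
#'   (gives the spread that questionnaire correlations and magnitude
#'   prediction are planted against).
#' @param onset_day days after treatment start before analgesia appears.
#' @param washout_carryover fraction of analgesia retained in washout
#'   (default 1: full retention).
#' @param rating_noise_sd within-subject rating noise (VAS units).
#' @param rating_ar1 lag-1 autocorrelation of the rating noise (default 0,
#'   white noise).
#' @param miss_prob probability a scheduled rating is absent.
#' @param n_subscales number of questionnaire subscales (default 38).
#' @param planted_subscale_effects data frame `subscale` (index), `r`
#'   (target correlation with %analgesia); `NULL` for no planted effects.
#' @param qs_miss_prob probability a subscale score is missing.
#' @param n_nodes connectivity nodes (default 122).
#' @param n_factors latent factors (communities) of the connectivity
#'   generator.
#' @param planted_edges data frame `i`, `j` (node indices), `dz` (group
#'   mean difference in Fisher z for responders), `persistent` (logical:
#'   FALSE restricts the offset to the pre-treatment scan V2).
#' @param conn_samples time-series samples per connectivity draw.
#' @param conn_loading_sd between-subject SD of the latent-factor loadings.
#' @param asymmetry_effect rightward offset of the subcortical right/left
#'   volume ratio in responders.
#' @param seed integer seed (mandatory; the whole cohort is reproducible
#'   from it).
#' @return validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_ptx = 43, n_notx = 20,
                          responder_fraction_ptx = 24 / 43,
                          responder_fraction_notx = 4 / 20,
                          baseline_mean = 6.1, baseline_sd = 1.33,
                          analgesia_pct = 33, analgesia_pct_sd = 10,
                          onset_day = 1, washout_carryover = 1,
                          rating_noise_sd = 1, rating_ar1 = 0,
                          miss_prob = 0.1,
                          n_subscales = 38,
                          planted_subscale_effects = data.frame(
                            subscale = 1:6,
                            r = c(0.6, 0.6, 0.5, 0.5, 0.45, 0.4)),
                          qs_miss_prob = 0.02,
                          n_nodes = 122, n_factors = 6,
                          planted_edges = data.frame(
                            i = c(5L, 17L, 40L), j = c(30L, 80L, 101L),
                            dz = c(0.3, -0.3, -0.3),
                            persistent = c(TRUE, TRUE, FALSE)),
                          conn_samples = 200, conn_loading_sd = 0.1,
                          asymmetry_effect = 0.05,
                          seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  p <- list(n_ptx = stopifnot_count(n_ptx, "n_ptx", 0L),
            n_notx = stopifnot_count(n_notx, "n_notx", 0L),
            responder_fraction_ptx = responder_fraction_ptx,
            responder_fraction_notx = responder_fraction_notx,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            analgesia_pct = analgesia_pct,
            analgesia_pct_sd = analgesia_pct_sd,
            onset_day = onset_day, washout_carryover = washout_carryover,
            rating_noise_sd = rating_noise_sd, rating_ar1 = rating_ar1,
            miss_prob = miss_prob,
            n_subscales = stopifnot_count(n_subscales, "n_subscales", 1L),
            planted_subscale_effects = planted_subscale_effects,
            qs_miss_prob = qs_miss_prob,
            n_nodes = stopifnot_count(n_nodes, "n_nodes", 2L),
            n_factors = stopifnot_count(n_factors, "n_factors", 1L),
            planted_edges = planted_edges,
            conn_samples = stopifnot_count(conn_samples, "conn_samples", 10L),
            conn_loading_sd = conn_loading_sd,
            asymmetry_effect = asymmetry_effect,
            seed = stopifnot_count(seed, "seed", 0L))
  stopifnot_scalar_prob(p$responder_fraction_ptx, "responder_fraction_ptx")
  stopifnot_scalar_prob(p$responder_fraction_notx, "responder_fraction_notx")
  stopifnot_scalar_prob(p$miss_prob, "miss_prob")
  stopifnot_scalar_prob(p$washout_carryover, "washout_carryover")
  stopifnot_scalar_prob(p$qs_miss_prob, "qs_miss_prob")
  if (p$analgesia_pct < 0) stop("analgesia_pct must be >= 0", call. = FALSE)
  if (p$baseline_sd < 0 || p$rating_noise_sd < 0 || p$analgesia_pct_sd < 0)
    stop("scale parameters must be >= 0", call. = FALSE)
  if (!is.null(p$planted_edges) && nrow(p$planted_edges)) {
    pe <- p$planted_edges
    if (any(pe$i < 1 | pe$j < 1 | pe$i > p$n_nodes | pe$j > p$n_nodes) ||
        any(pe$i == pe$j))
      stop("planted edge indices must be distinct and within 1..n_nodes",
           call. = FALSE)
    if (anyDuplicated(cbind(pmin(pe$i, pe$j), pmax(pe$i, pe$j))))
      stop("planted edges must be distinct", call. = FALSE)
  }
  if (!is.null(p$planted_subscale_effects) &&
      nrow(p$planted_subscale_effects)) {
    ps <- p$planted_subscale_effects
    if (any(ps$subscale < 1 | ps$subscale > p$n_subscales) ||
        anyDuplicated(ps$subscale) || any(abs(ps$r) >= 1))
      stop("invalid planted subscale effects", call. = FALSE)
  }
  class(p) <- "cohort_params"
  p
}

# Canonical visit-date schedule relative to a trial start date.
visit_schedule <- function(start = as.Date("2015-01-05")) {
  start + cumsum(c(0L, unname(PERIOD_DAYS)))   # visits 1..6
}

# Simulate one subject's rating stream over the full schedule.
# analgesia_pct here is the subject's own planted value (0 for null).
simulate_ratings <- function(subject_id, baseline_level, analgesia_pct,
                             params, visit_dates, seed) {
  days <- as.integer(visit_dates[6] - visit_dates[1])   # 56
  with_seed(seed, {
    day_idx <- rep(seq_len(days) - 1L, each = 2L)
    slot <- rep(c(9, 21), times = days)
    jitter_h <- runif(length(slot), -2, 2)
    ts <- as.POSIXct(visit_dates[1], tz = "UTC") +
      (day_idx * 24 + slot + jitter_h) * 3600
    # expected level per entry, driven by the period the entry falls in
    vb <- as.numeric(visit_dates - visit_dates[1])
    period <- findInterval(day_idx + (slot + jitter_h) / 24, vb)
    frac <- analgesia_pct / 100
    eff <- numeric(length(ts))
    t1_on <- vb[2] + params$onset_day; t2_on <- vb[4] + params$onset_day
    tday <- day_idx + (slot + jitter_h) / 24
    eff[period == 2 & tday >= t1_on] <- frac
    eff[period == 4 & tday >= t2_on] <- frac
    eff[period %in% c(3, 5)] <- frac * params$washout_carryover
    mu <- baseline_level * (1 - eff)
    noise <- rnorm(length(ts), 0, params$rating_noise_sd)
    if (params$rating_ar1 != 0) {
      rho <- params$rating_ar1
      for (k in 2:length(noise))
        noise[k] <- rho * noise[k - 1] + sqrt(1 - rho^2) * noise[k]
    }
    vas <- pmin(10, pmax(0, mu + noise))
    keep <- runif(length(ts)) >= params$miss_prob
    data.frame(subject_id = subject_id, timestamp = ts[keep],
               vas = vas[keep], stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' Draws arm assignment, true responder labels, planted per-subject
#' %analgesia, full rating streams, questionnaire subscales (Gaussian
#' copula with planted correlations to the planted analgesia), per-visit
#' connectivity matrices and subcortical volume tables. Byte-identical
#' given the same parameters and seed.
#'
#' @param params a [cohort_params()] object.
#' @param include_brain generate connectivity matrices and volumes
#'   (default TRUE; FALSE skips the heavier imaging component).
#' @return list of class `synthetic_cohort`: `subjects`, `ratings`,
#'   `visits`, `questionnaires`, `connectivity` (list subject -> scan visit
#'   -> matrix), `volumes`, `params`.
#' @export
generate_cohort <- function(params, include_brain = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  vd <- visit_schedule()
  ids <- c(sprintf("PTX%03d", seq_len(params$n_ptx)),
           sprintf("NTX%03d", seq_len(params$n_notx)))
  arm <- rep(c("PTx", "NoTx"), c(params$n_ptx, params$n_notx))

  subjects <- with_seed(params$seed, {
    # exact responder counts per arm (rounded), randomly positioned
    draw_resp <- function(n, frac) {
      r <- logical(n)
      if (n > 0L) r[sample.int(n, round(frac * n))] <- TRUE
      r
    }
    resp <- c(draw_resp(params$n_ptx, params$responder_fraction_ptx),
              draw_resp(params$n_notx, params$responder_fraction_notx))
    bl <- rnorm(length(ids), params$baseline_mean, params$baseline_sd)
    bl <- pmin(9.5, pmax(4, bl))          # inclusion criterion: > 4/10
    an <- ifelse(resp,
                 pmin(80, pmax(5, rnorm(length(ids), params$analgesia_pct,
                                        params$analgesia_pct_sd))),
                 rnorm(length(ids), 0, 2))
    data.frame(subject_id = ids, arm = arm, true_responder = resp,
               baseline_level = bl, true_analgesia_pct = an,
               age = round(pmin(75, pmax(21, rnorm(length(ids), 45, 12)))),
               sex = sample(c("F", "M"), length(ids), replace = TRUE),
               stringsAsFactors = FALSE)
  })

  ratings <- do.call(rbind, lapply(seq_along(ids), function(k) {
    simulate_ratings(ids[k], subjects$baseline_level[k],
                     subjects$true_analgesia_pct[k], params, vd,
                     derive_seed(params$seed, paste0("ratings:", ids[k])))
  }))

  visits <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (v in 1:6) visits[[paste0("visit_", v)]] <- vd[v]

  questionnaires <- generate_questionnaires(params, subjects)

  connectivity <- NULL
  volumes <- NULL
  if (include_brain) {
    connectivity <- lapply(seq_along(ids), function(k) {
      grp <- if (subjects$arm[k] == "PTx" && subjects$true_responder[k])
        "responder" else "nonresponder"
      out <- lapply(SCAN_VISITS, function(v)
        generate_connectivity(params, grp, v,
                              seed = derive_seed(params$seed,
                                                 paste0("conn:", ids[k], v))))
      names(out) <- SCAN_VISITS
      out
    })
    names(connectivity) <- ids
    volumes <- generate_volumes(params, subjects)
  }

  structure(list(subjects = subjects, ratings = ratings, visits = visits,
                 questionnaires = questionnaires,
                 connectivity = connectivity, volumes = volumes,
                 params = params, seed = params$seed),
            class = "synthetic_cohort")
}

# Questionnaire subscales via a Gaussian copula: each subscale's latent is
# rho * (standardized planted analgesia) + sqrt(1-rho^2) * noise, then
# mapped through a Beta(2, 2) margin onto a 0-40 score range, so margins
# are non-normal yet carry the target correlations. The association is
# planted in the placebo arm only: psychological traits predispose to
# *placebo* response, so no-treatment subjects carry no association
# between their subscales and their (natural-history) analgesia.
generate_questionnaires <- function(params, subjects) {
  n <- nrow(subjects)
  rho <- numeric(params$n_subscales)
  pse <- params$planted_subscale_effects
  if (!is.null(pse) && nrow(pse)) rho[pse$subscale] <- pse$r
  a <- as.numeric(scale(subjects$true_analgesia_pct))
  if (anyNA(a)) a <- rep(0, n)   # degenerate: no spread in planted analgesia
  a[subjects$arm == "NoTx"] <- with_seed(
    derive_seed(params$seed, "notx-latent"),
    rnorm(sum(subjects$arm == "NoTx")))
  with_seed(derive_seed(params$seed, "questionnaires"), {
    z <- vapply(seq_len(params$n_subscales), function(j)
      rho[j] * a + sqrt(1 - rho[j]^2) * rnorm(n), numeric(n))
    val <- qbeta(pnorm(z), 2, 2) * 40
    if (params$qs_miss_prob > 0)
      val[matrix(runif(length(val)) < params$qs_miss_prob,
                 nrow = n)] <- NA_real_
    colnames(val) <- sprintf("sc%02d", seq_len(params$n_subscales))
    cbind(data.frame(subject_id = subjects$subject_id,
                     stringsAsFactors = FALSE),
          as.data.frame(val))
  })
}

# Deterministic group-level factor loadings for the connectivity generator.
conn_loadings <- function(params) {
  with_seed(derive_seed(params$seed, "conn-loadings"), {
    n <- params$n_nodes; k <- params$n_factors
    block <- rep_len(seq_len(k), n)
    L <- matrix(0, n, k)
    L[cbind(seq_len(n), block)] <- runif(n, 0.5, 0.8)
    L
  })
}

#' Generate one subject-visit connectivity matrix
#'
#' A latent-factor (community-structured) population correlation matrix is
#' perturbed per subject (loading jitter), planted group offsets are added
#' in Fisher-z space at the parameterized edges (responder group only;
#' non-persistent edges only at the pre-treatment scan `"V2"`), and the
#' returned matrix is the sample correlation of `conn_samples` multivariate
#' normal draws -- a valid (symmetric, unit-diagonal, positive
#' semi-definite) correlation matrix by construction.
#'
#' @param params a [cohort_params()] object.
#' @param subject_group `"responder"` or `"nonresponder"`.
#' @param visit one of `"V2"`, `"V3"`, `"V4"`, `"V5"`.
#' @param seed integer seed for the subject-level draw.
#' @return correlation matrix with node ids `n001`, `n002`, ...
#' @export
generate_connectivity <- function(params, subject_group, visit,
                                  seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  subject_group <- match.arg(subject_group, c("responder", "nonresponder"))
  visit <- match.arg(visit, SCAN_VISITS)
  L <- conn_loadings(params)
  n <- params$n_nodes
  with_seed(seed, {
    Ls <- L + matrix(rnorm(length(L), 0, params$conn_loading_sd),
                     nrow(L), ncol(L))
    d <- pmax(0.05, 1 - rowSums(Ls^2))
    R <- tcrossprod(Ls) + diag(d)
    R <- stats::cov2cor(R)
    pe <- params$planted_edges
    if (subject_group == "responder" && !is.null(pe) && nrow(pe)) {
      active <- pe$persistent | visit == "V2"
      if (any(active)) {
        Z <- fisher_z(R)
        for (e in which(active)) {
          Z[pe$i[e], pe$j[e]] <- Z[pe$i[e], pe$j[e]] + pe$dz[e]
          Z[pe$j[e], pe$i[e]] <- Z[pe$j[e], pe$i[e]] + pe$dz[e]
        }
        R <- fisher_r(Z)
      }
    }
    # planted offsets can break positive semi-definiteness; repair by
    # eigenvalue clipping, then renormalize the diagonal
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      vals <- pmax(ev$values, 1e-6)
      R <- stats::cov2cor(ev$vectors %*% diag(vals) %*% t(ev$vectors))
    }
    X <- matrix(rnorm(params$conn_samples * n), params$conn_samples) %*%
      chol(R)
    out <- cor(X)
    dimnames(out) <- list(sprintf("n%03d", seq_len(n)),
                          sprintf("n%03d", seq_len(n)))
    out
  })
}

# Subcortical volume tables (mm^3) per subject and scan visit, with the
# responder group's right/left ratio offset by asymmetry_effect.
generate_volumes <- function(params, subjects) {
  with_seed(derive_seed(params$seed, "volumes"), {
    rows <- lapply(seq_len(nrow(subjects)), function(k) {
      resp <- subjects$arm[k] == "PTx" && subjects$true_responder[k]
      left <- c(nac = rnorm(1, 550, 45), amy = rnorm(1, 1700, 130),
                hip = rnorm(1, 4100, 300))
      ratio <- 1 + (if (resp) params$asymmetry_effect else 0) +
        rnorm(1, 0, 0.02)
      right <- left * ratio
      pgm <- rnorm(1, 6e5, 5e4)
      do.call(rbind, lapply(SCAN_VISITS, function(v) {
        m <- rnorm(6, 1, 0.005)   # per-visit measurement noise
        data.frame(subject_id = subjects$subject_id[k], visit = v,
                   nac_l = left["nac"] * m[1], nac_r = right["nac"] * m[2],
                   amy_l = left["amy"] * m[3], amy_r = right["amy"] * m[4],
                   hip_l = left["hip"] * m[5], hip_r = right["hip"] * m[6],
                   peripheral_gm = pgm,
                   age = subjects$age[k], sex = subjects$sex[k],
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate stationary null rating series
#'
#' All five periods are drawn from the identical stationary distribution
#' (no treatment effect anywhere) -- the type-I calibration input for the
#' responder classifier.
#'
#' @param n_subjects number of subjects (0 gives an empty list).
#' @param params a [cohort_params()] object (its analgesia parameters are
#'   ignored; baseline and noise parameters are used).
#' @return list of per-subject data frames with `subject_id`, `timestamp`,
#'   `vas`, `period`.
#' @export
generate_null_ratings <- function(n_subjects, params) {
  n_subjects <- stopifnot_count(n_subjects, "n_subjects")
  if (n_subjects == 0L) return(list())
  stopifnot(inherits(params, "cohort_params"))
  vd <- visit_schedule()
  lapply(seq_len(n_subjects), function(k) {
    id <- sprintf("NULL%04d", k)
    s <- derive_seed(params$seed, paste0("null:", id))
    bl <- with_seed(s + 1L,
                    pmin(9.5, pmax(4, rnorm(1, params$baseline_mean,
                                            params$baseline_sd))))
    r <- simulate_ratings(id, bl, 0, params, vd, s)
    assign_periods(r, vd)
  })
}
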