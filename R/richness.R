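#' Incidence summary of a presence/absence table
#'
#' @param presence Logical or 0/1 matrix (features x samples); a count matrix
#'   is accepted and thresholded at > 0.
#' @return A list of class `incidence_summary` with `S_obs` (features present
#'   in at least one sample), `f1` (seen in exactly one sample) and `f2`
#'   (seen in exactly two).
#' @export
incidence_summary <- function(presence) {
  inc <- rowSums(presence > 0)
  structure(list(S_obs = sum(inc >= 1L), f1 = sum(inc == 1L),
                 f2 = sum(inc == 2L)), class = "incidence_summary")
}

#' Chao1 richness estimator
#'
#' Bias-corrected incidence-based Chao1:
#' `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))`, which is defined for `f2 = 0`
#' and never falls below `S_obs`. The classical form `S_obs + f1^2 / (2 f2)`
#' is available with `bias_corrected = FALSE` (it requires `f2 > 0`).
#'
#' @param inc An `incidence_summary`, or `S_obs` as a number when `f1`/`f2`
#'   are given directly.
#' @param f1,f2 Singleton and doubleton counts (ignored when `inc` is an
#'   `incidence_summary`).
#' @param bias_corrected Use the bias-corrected form (default TRUE).
#' @return Estimated total richness (numeric scalar, >= `S_obs`).
#' @export
chao1 <- function(inc, f1 = NULL, f2 = NULL, bias_corrected = TRUE) {
  if (inherits(inc, "incidence_summary")) {
    S_obs <- inc$S_obs; f1 <- inc$f1; f2 <- inc$f2
  } else S_obs <- inc
  if (f1 + f2 > S_obs || S_obs < 0 || f1 < 0 || f2 < 0)
    stop("invalid incidence summary (need f1 + f2 <= S_obs, all >= 0)")
  if (bias_corrected) S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else {
    if (f2 == 0) stop("classical Chao1 undefined for f2 = 0; use the bias-corrected form")
    S_obs + f1^2 / (2 * f2)
  }
}

#' Sample-based rarefaction curve of Chao1 richness
#'
#' For each sample count `m` from 1 to the cohort size, draws `m` samples
#' with replacement from the cohort, computes Chao1 on the incidence of the
#' drawn multiset (a sample drawn twice contributes two incidences), and
#' repeats; the curve reports the mean and s.d. of the estimate per `m`.
#'
#' @param presence Features x samples presence (or count) matrix.
#' @param repetitions Resampling repetitions per `m` (default 100).
#' @param seed Integer seed.
#' @param bias_corrected Passed to [chao1()].
#' @return A data.frame of class `rarefaction_curve` with columns `m`,
#'   `mean`, `sd` (the Chao1 estimate across repetitions) and `s_obs_mean`
#'   (mean observed richness of the drawn samples — the classical
#'   saturation-curve axis, non-decreasing in `m`); attribute `repetitions`.
#'   Note that the Chao1 estimate targets the total richness at every `m`,
#'   so its mean is roughly flat (and strongly upward-biased at `m = 1`,
#'   where every observed feature is a singleton) rather than saturating.
#' @export
rarefy <- function(presence, repetitions = 100L, seed = 1L,
                   bias_corrected = TRUE) {
  if (ncol(presence) < 1L) stop("need at least one sample")
  if (repetitions <= 0L) stop("repetitions must be positive")
  pres <- presence > 0
  n <- ncol(pres)
  with_seed(seed, {
    out <- lapply(seq_len(n), function(m) {
      est <- vapply(seq_len(repetitions), function(r) {
        draw <- sample.int(n, m, replace = TRUE)
        inc <- rowSums(pres[, draw, drop = FALSE])
        c(chao1(sum(inc >= 1L), sum(inc == 1L), sum(inc == 2L),
                bias_corrected = bias_corrected),
          sum(inc >= 1L))
      }, numeric(2))
      data.frame(m = m, mean = mean(est[1, ]), sd = stats::sd(est[1, ]),
                 s_obs_mean = mean(est[2, ]))
    })
    res <- do.call(rbind, out)
    attr(res, "repetitions") <- repetitions
    class(res) <- c("rarefaction_curve", class(res))
    res
  })
}

#' Estimated coverage of a catalog
#'
#' Percent of the estimated total richness that was observed:
#' `100 * observed / estimated`.
#'
#' @param observed Observed feature count (> 0).
#' @param estimated Estimated total richness (>= observed).
#' @return Coverage in percent.
#' @export
coverage <- function(observed, estimated) {
  if (observed <= 0) stop("observed must be positive")
  if (estimated < observed) stop("estimated richness below observed count")
  100 * observed / estimated
}
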