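#' Configuration for the synthetic labeling experiment
#'
#' The generator emulates the medium-switch experiment: a trajectory of the
#' four Tri->KR isotopologue abundances over one generation, sampled at the
#' switch and four chase times, in several biological replicates, with
#' multiplicative (log-normal) intensity noise and ppm-scale mass error on
#' the peak positions. It does not emulate chromatography, isotope
#' envelopes, fragmentation efficiency, or replicate-specific growth rates.
#'
#' @param params [kinetic_params()] of the simulated genotype.
#' @param times Sampling times in minutes (default c(0, 15, 30, 45, 60):
#'   the switch plus four chase points spanning one generation).
#' @param n_replicates Biological replicates (default 4, within the 3-5
#'   used experimentally).
#' @param scenario Simulation scenario (default `"cohort"`, the
#'   balanced-growth configuration that reproduces the observed dilution
#'   behavior; see [initial_state()]).
#' @param intensity_scale Total ion intensity per sample (arbitrary units).
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (default 0.10).
#' @param ppm_sd SD of the Gaussian relative mass error in ppm (default 5).
#' @param seed Integer seed; mandatory, all outputs regenerate
#'   bit-identically from (config, seed).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(params, times = c(0, 15, 30, 45, 60),
                             n_replicates = 4, scenario = "cohort",
                             intensity_scale = 1e5, cv = 0.10, ppm_sd = 5,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(inherits(params, "kinetic_params"), n_replicates >= 1,
            cv >= 0, ppm_sd >= 0, length(times) >= 2)
  structure(list(params = params, times = sort(times),
                 n_replicates = as.integer(n_replicates),
                 scenario = scenario,
                 intensity_scale = intensity_scale, cv = cv,
                 ppm_sd = ppm_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

.lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic isotopologue intensity time course
#'
#' Simulates the noiseless trajectory with the deterministic engine,
#' converts relative abundances to per-replicate intensities
#' (scale x abundance x log-normal factor, independently per isotopologue,
#' replicate and time), and quantifies them back to per-replicate relative
#' abundances. With cv = 0 the per-replicate abundances equal the
#' noiseless trajectory exactly.
#'
#' @param config [synthetic_config()].
#' @return list with `quant` (data.frame time_min, replicate, nn, oo, on,
#'   no in percent), `intensities` (same shape, raw intensities), and
#'   `truth` (generating params, scenario, seed and the noiseless
#'   trajectory quant).
#' @export
generate_timecourse <- function(config) {
  set.seed(config$seed)
  traj <- simulate_pools(config$params, times = config$times,
                         scenario = config$scenario)
  tq <- trajectory_quant(traj)
  iso <- c("nn", "oo", "on", "no")
  rows <- list(); ints <- list()
  k <- 0
  for (i in seq_along(config$times)) {
    for (r in seq_len(config$n_replicates)) {
      fac <- .lognormal_factors(4, config$cv)
      I <- config$intensity_scale * unlist(tq[i, iso]) / 100 * fac
      q <- relative_abundance(setNames(I, iso))
      k <- k + 1
      rows[[k]] <- data.frame(time_min = config$times[i],
                              replicate = paste0("rep", r),
                              nn = q[["nn"]], oo = q[["oo"]],
                              on = q[["on"]], no = q[["no"]])
      ints[[k]] <- data.frame(time_min = config$times[i],
                              replicate = paste0("rep", r),
                              nn = I[["nn"]], oo = I[["oo"]],
                              on = I[["on"]], no = I[["no"]])
    }
  }
  list(quant = do.call(rbind, rows),
       intensities = do.call(rbind, ints),
       truth = list(params = config$params, scenario = config$scenario,
                    seed = config$seed, trajectory = tq))
}

#' Generate synthetic MS1 and MS2 peak lists
#'
#' For every sample and isotopologue with non-zero intensity, emits one MS1
#' peak at the theoretical parental mass of that label state (plus Gaussian
#' ppm error) carrying the noisy intensity, and the seven MS2 fragment
#' peaks of that isotopologue's column of the theoretical table, with
#' uniform relative fragment intensities (assignment uses masses only).
#'
#' @param config [synthetic_config()].
#' @return list with `ms1` and `ms2` peak data.frames (columns mz,
#'   intensity, level, time_min, replicate, precursor_mz) and the
#'   underlying `timecourse`.
#' @export
generate_peaklists <- function(config) {
  tc <- generate_timecourse(config)  # consumes the seed-determined noise
  tab <- theoretical_table()
  iso <- c("nn", "oo", "on", "no")
  ms1 <- list(); ms2 <- list()
  k <- 0
  for (i in seq_len(nrow(tc$intensities))) {
    row <- tc$intensities[i, ]
    for (s in iso) {
      I <- row[[s]]
      if (I <= 0) next
      k <- k + 1
      pmz <- tab[1, s] * (1 + stats::rnorm(1, 0, config$ppm_sd * 1e-6))
      ms1[[k]] <- data.frame(mz = pmz, intensity = I, level = "MS1",
                             time_min = row$time_min,
                             replicate = row$replicate,
                             precursor_mz = NA_real_)
      fmz <- tab[, s] * (1 + stats::rnorm(7, 0, config$ppm_sd * 1e-6))
      ms2[[k]] <- data.frame(mz = fmz, intensity = I / 7, level = "MS2",
                             time_min = row$time_min,
                             replicate = row$replicate,
                             precursor_mz = pmz)
    }
  }
  list(ms1 = do.call(rbind, ms1), ms2 = do.call(rbind, ms2),
       timecourse = tc)
}

#' Quantify a synthetic (or real) MS1 peak list
#'
#' Matches MS1 peaks against the parental isotopologue quartet and computes
#' per-replicate relative abundances; the zero-noise round trip
#' generate -> assign -> quantify reproduces the generating abundances
#' exactly.
#'
#' @param ms1 MS1 peak data.frame (columns mz, intensity, time_min,
#'   replicate).
#' @param tol_ppm Matching tolerance (default 20 ppm).
#' @return data.frame as from [quantify_assignments()].
#' @export
quantify_peaklist <- function(ms1, tol_ppm = 20) {
  tab <- theoretical_table()
  quartet <- data.frame(fragment = rownames(tab)[1],
                        isotopologue = colnames(tab),
                        mass = tab[1, ], stringsAsFactors = FALSE)
  quantify_assignments(match_peaks(ms1, quartet, tol_ppm = tol_ppm))
}
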