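#' Exact stochastic simulation of the tethering/hydrolysis network
#'
#' Direct-method (Gillespie) simulation of the same reaction network as
#' [pool_derivatives()], at integer molecule counts: Lpp synthesis
#' (rate mu L), donor synthesis (mu delta L, septal-scaled), the four
#' tethering channels (k_t F_y D_x / (D_o + D_n)) and the four hydrolysis
#' channels (k_h B_xy). Used as an independent oracle for the deterministic
#' engine on down-scaled instances; at 1e6 copies per cell the mean-field
#' ODE is the appropriate primary engine.
#'
#' @param params [kinetic_params()]; set `lpp_copies` to the desk-scale N.
#' @param times Output grid (min); the state is recorded at each grid time.
#' @param scenario,init As in [simulate_pools()]; the initial state is
#'   rounded to integers.
#' @param seed Optional integer seed (fixed seed gives a bit-identical
#'   event sequence).
#' @return data.frame of class `lpp_trajectory` (time plus nine pools).
#' @export
simulate_gillespie <- function(params, times = seq(0, 60, by = 1),
                               scenario = "switch", init = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (is.null(init)) init <- initial_state(p, scenario)
  y <- round(init)
  S <- y[["S"]]  # stems tracked deterministically alongside
  y <- y[1:8]
  rec <- matrix(NA_real_, nrow = length(times), ncol = 9,
                dimnames = list(NULL, .pool_names))
  # state-change vectors for the 10 channels, over pools 1..8
  # order: syn Lpp, syn donor, tether oo,on,no,nn (stem,lpp), hydro oo,on,no,nn
  V <- matrix(0L, nrow = 10, ncol = 8)
  colnames(V) <- .pool_names[1:8]
  V[1, "F_n"] <- 1L
  V[2, "D_n"] <- 1L
  V[3, c("F_o", "D_o", "B_oo")] <- c(-1L, -1L, 1L)
  V[4, c("F_n", "D_o", "B_on")] <- c(-1L, -1L, 1L)
  V[5, c("F_o", "D_n", "B_no")] <- c(-1L, -1L, 1L)
  V[6, c("F_n", "D_n", "B_nn")] <- c(-1L, -1L, 1L)
  V[7, c("B_oo", "F_o")] <- c(-1L, 1L)
  V[8, c("B_on", "F_n")] <- c(-1L, 1L)
  V[9, c("B_no", "F_o")] <- c(-1L, 1L)
  V[10, c("B_nn", "F_n")] <- c(-1L, 1L)

  t <- times[1]
  irec <- 1L
  rec[1, ] <- c(y, S)
  t_end <- times[length(times)]
  while (t < t_end) {
    L <- sum(y[1:6])
    Dtot <- y[["D_o"]] + y[["D_n"]]
    p_o <- if (Dtot > 0) y[["D_o"]] / Dtot else 0
    a <- c(p$mu * L,
           p$mu * p$delta * L * p$septal_factor,
           p$k_t * y[["F_o"]] * p_o,
           p$k_t * y[["F_n"]] * p_o,
           p$k_t * y[["F_o"]] * (1 - p_o),
           p$k_t * y[["F_n"]] * (1 - p_o),
           p$k_h * y[["B_oo"]], p$k_h * y[["B_on"]],
           p$k_h * y[["B_no"]], p$k_h * y[["B_nn"]])
    a0 <- sum(a)
    t_next <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
    while (irec < length(times) && times[irec + 1] <= min(t_next, t_end)) {
      irec <- irec + 1L
      rec[irec, ] <- c(y, S * exp(p$mu * (times[irec] - times[1])))
    }
    if (t_next > t_end) break
    j <- sample.int(10L, 1L, prob = a)
    y <- y + V[j, ]
    t <- t_next
  }
  while (irec < length(times)) {
    irec <- irec + 1L
    rec[irec, ] <- c(y, S * exp(p$mu * (times[irec] - times[1])))
  }
  out <- cbind(data.frame(time = times), as.data.frame(rec))
  class(out) <- c("lpp_trajectory", "data.frame")
  out
}
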