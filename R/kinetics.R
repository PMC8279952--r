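# Discrete-generation model of CpG-dyad methylation inheritance.
#
# A dyad state is (plus strand, minus strand) in {U, M}^2, ordered
# UU, MU, UM, MM. Each cell division a daughter inherits one parental
# strand (either with probability 1/2): existing marks on the inherited
# strand persist with probability 1 - lam and unmethylated parental sites
# gain with probability delta_p; the nascent strand is methylated with
# probability mu when the (post-event) parental template C is methylated,
# otherwise with probability delta_n. Bisulfite observation errors act per
# strand: U read as M with probability e, M read as U with probability c.

#' One cell division of the dyad distribution
#'
#' Applies the maintenance/de novo transition law to a dyad-state
#' distribution and returns the distribution after one division,
#' averaging over which parental strand the daughter inherits.
#'
#' @param p numeric distribution over (UU, MU, UM, MM).
#' @param params a [kinetic_params()].
#' @return Distribution over the 4 dyad states after one division.
#' @export
transition_step <- function(p, params) {
  stopifnot(inherits(params, "kinetic_params"))
  p <- as.numeric(p)
  if (length(p) != 4 || any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("transition_step: p must be a distribution over the 4 dyad states")
  T1 <- transition_matrix(params)
  setNames(as.numeric(T1 %*% p), DYAD_STATES)
}

# Column-stochastic 4x4 one-division matrix: entry [to, from].
transition_matrix <- function(params) {
  mu <- params$mu; dn <- params$delta_n; dp <- params$delta_p
  lam <- params$lam
  # template state after loss/parental-de-novo events:
  # P(template M | parental strand was M) and (| was U)
  # daughter dyad distribution given the inherited parental strand state
  # and which daughter strand (plus/minus) the template occupies. The
  # nascent strand reads the post-loss template state; parental de novo
  # gain (delta_p) acts on the template strand afterwards, independently.
  daughter <- function(s_meth, template_is_plus) {
    p_postloss_M <- if (s_meth) 1 - lam else 0
    out <- numeric(4)
    for (pl in 0:1) {  # post-loss template state
      w <- if (pl == 1) p_postloss_M else 1 - p_postloss_M
      if (w == 0) next
      p_tm <- if (pl == 1) 1 else dp      # final template methylated
      p_nas <- if (pl == 1) mu else dn    # nascent methylated
      for (tm in 0:1) for (nm in 0:1) {
        pt <- if (tm == 1) p_tm else 1 - p_tm
        pn <- if (nm == 1) p_nas else 1 - p_nas
        plus <- if (template_is_plus) tm else nm
        minus <- if (template_is_plus) nm else tm
        idx <- 1 + plus + 2 * minus  # UU=1, MU=2, UM=3, MM=4
        out[idx] <- out[idx] + w * pt * pn
      }
    }
    out
  }
  Tm <- matrix(0, 4, 4, dimnames = list(DYAD_STATES, DYAD_STATES))
  for (from in 1:4) {
    plus_m <- (from - 1) %% 2 == 1   # MU=2, MM=4 have plus methylated
    minus_m <- from > 2              # UM=3, MM=4 have minus methylated
    Tm[, from] <- 0.5 * daughter(plus_m, TRUE) + 0.5 * daughter(minus_m, FALSE)
  }
  Tm
}

iterate_transition <- function(p, params, n) {
  if (n == 0) return(setNames(as.numeric(p), DYAD_STATES))
  Tm <- transition_matrix(params)
  for (i in seq_len(n)) p <- Tm %*% p
  setNames(as.numeric(p), DYAD_STATES)
}

#' Per-strand methylation marginal of a dyad distribution
#'
#' @param p distribution over (UU, MU, UM, MM).
#' @return Probability that a randomly chosen strand of the dyad is
#'   methylated.
#' @export
strand_marginal <- function(p) {
  p <- as.numeric(p)
  p[4] + (p[2] + p[3]) / 2
}

#' Equilibrium per-strand methylation level
#'
#' With `delta_p = lam = 0` the marginal obeys
#' `f' = (f (1 + mu) + (1 - f) delta_n) / 2`, whose fixed point is
#' `f* = delta_n / (1 - mu + delta_n)`. The general case is solved by
#' iterating the full dyad dynamics to a fixed point.
#'
#' @param params a [kinetic_params()].
#' @param tol convergence tolerance on the dyad distribution.
#' @param max_iter iteration cap.
#' @return list with `f_star` (equilibrium per-strand methylation),
#'   `p_star` (equilibrium dyad distribution, `NULL` if only the closed
#'   form applies), and `unique` (FALSE at the non-contractive corner
#'   mu = 1, delta_n = 0 where every marginal is conserved).
#' @export
stationary_marginal <- function(params, tol = 1e-12, max_iter = 100000) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$delta_p == 0 && params$lam == 0 &&
      params$mu >= 1 && params$delta_n <= 0) {
    return(list(f_star = NA_real_, p_star = NULL, unique = FALSE,
                note = "marginal conserved: no unique fixed point"))
  }
  closed <- if (params$delta_p == 0 && params$lam == 0)
    params$delta_n / (1 - params$mu + params$delta_n) else NA_real_
  Tm <- transition_matrix(params)
  p <- rep(0.25, 4)
  for (i in seq_len(max_iter)) {
    p2 <- as.numeric(Tm %*% p)
    if (max(abs(p2 - p)) < tol) {
      p <- p2
      break
    }
    p <- p2
  }
  f <- strand_marginal(p)
  if (!is.na(closed)) f <- closed  # exact closed form preferred when valid
  list(f_star = f, p_star = setNames(p, DYAD_STATES), unique = TRUE)
}

#' Per-strand bisulfite observation error matrix
#'
#' @param e conversion failure: true U observed as M.
#' @param c inappropriate conversion: true M observed as U.
#' @return 4x4 row-stochastic matrix `O[true, observed]` assuming
#'   independent per-strand errors.
#' @export
observation_matrix <- function(e, c) {
  if (any(c(e, c) < 0) || any(c(e, c) > 1))
    stop("observation_matrix: e and c must be in [0, 1]")
  # per-strand P(observed | true): rows true U, M; cols observed U, M
  S <- matrix(c(1 - e, e, c, 1 - c), nrow = 2, byrow = TRUE,
              dimnames = list(c("U", "M"), c("U", "M")))
  O <- matrix(0, 4, 4, dimnames = list(DYAD_STATES, DYAD_STATES))
  for (ti in 1:4) for (oi in 1:4) {
    tp <- substr(DYAD_STATES[ti], 1, 1); tm <- substr(DYAD_STATES[ti], 2, 2)
    op <- substr(DYAD_STATES[oi], 1, 1); om <- substr(DYAD_STATES[oi], 2, 2)
    O[ti, oi] <- S[tp, op] * S[tm, om]
  }
  O
}

#' Classify hairpin-bisulfite molecules into dyad-state counts
#'
#' Hairpin ligation links both strands of one molecule, so each molecule
#' yields a call for the plus and the minus strand at every dyad it covers.
#' Each dyad with two unambiguous calls increments exactly one of
#' UU/MU/UM/MM; ambiguous calls (anything other than "M"/"U") skip that
#' dyad. Molecules whose two strands report different numbers of dyads are
#' rejected and counted.
#'
#' @param molecules list of molecules, each a list with character vectors
#'   `plus` and `minus` of per-dyad calls ("M", "U", or other = ambiguous).
#' @param sample,class labels for the output row.
#' @return list with `counts` (a one-row [dyad_count_table()]),
#'   `n_rejected` molecules and `n_skipped_dyads`.
#' @export
classify_dyads <- function(molecules, sample = "s", class = "all") {
  n <- setNames(numeric(4), DYAD_STATES)
  rejected <- 0L
  skipped <- 0L
  for (mol in molecules) {
    if (length(mol$plus) != length(mol$minus)) {
      rejected <- rejected + 1L
      next
    }
    ok <- mol$plus %in% c("M", "U") & mol$minus %in% c("M", "U")
    skipped <- skipped + sum(!ok)
    st <- paste0(mol$plus[ok], mol$minus[ok])
    tab <- table(factor(st, levels = DYAD_STATES))
    n <- n + as.numeric(tab)
  }
  list(counts = dyad_count_table(sample, class, n["UU"], n["MU"],
                                 n["UM"], n["MM"]),
       n_rejected = rejected, n_skipped_dyads = skipped)
}

#' log2 fold change of dyad-state frequencies against a reference
#'
#' Per state s: `log2((f_s^sample + pseudo) / (f_s^ref + pseudo))` with
#' frequencies f = count / total. Default pseudocount is 1/total of the
#' smaller library, on the frequency scale.
#'
#' @param sample_row,ref_row single rows of a [dyad_count_table()].
#' @param pseudo frequency-scale pseudocount; `NULL` = 1/min(total).
#' @return Named numeric vector of per-state log2 fold changes.
#' @export
dyad_log2fc <- function(sample_row, ref_row, pseudo = NULL) {
  fs <- dyad_freqs(sample_row)
  fr <- dyad_freqs(ref_row)
  if (is.null(pseudo)) {
    tot_s <- sum(as.numeric(sample_row[c("n_UU", "n_MU", "n_UM", "n_MM")]))
    tot_r <- sum(as.numeric(ref_row[c("n_UU", "n_MU", "n_UM", "n_MM")]))
    pseudo <- 1 / min(tot_s, tot_r)
  }
  log2((fs + pseudo) / (fr + pseudo))
}

#' Time course of dyad observations
#'
#' @param labels character vector of timepoint labels.
#' @param divisions integer vector: cell divisions since the previous
#'   timepoint (first entry defines t = 0 and must be 0).
#' @param counts a [dyad_count_table()] with one row per timepoint, in
#'   order.
#' @return A `dyad_time_course` object.
#' @export
dyad_time_course <- function(labels, divisions, counts) {
  stopifnot(length(labels) == length(divisions),
            nrow(counts) == length(labels))
  divisions <- as.integer(divisions)
  if (any(divisions < 0)) stop("divisions must be >= 0")
  if (length(divisions) && divisions[1] != 0)
    stop("first timepoint defines t = 0 (divisions 0)")
  structure(list(labels = labels, divisions = divisions,
                 counts = counts), class = "dyad_time_course")
}

#' Log-likelihood of a dyad time course under the kinetic model
#'
#' The hidden dyad state starts at `params$p0`, advances by
#' `divisions_since_previous` transitions between consecutive timepoints,
#' and each timepoint's observed counts are multinomial under the
#' error-convolved state `t(O) %*% p`.
#'
#' @param params a [kinetic_params()].
#' @param tc a [dyad_time_course()].
#' @return Total log-likelihood (0 for an empty time course; `-Inf` if an
#'   observed state has probability zero, possible only when e = c = 0).
#' @export
dyad_loglik <- function(params, tc) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(tc, "dyad_time_course"))
  n_t <- length(tc$labels)
  if (n_t == 0) return(0)
  O <- observation_matrix(params$e, params$c)
  p <- params$p0
  ll <- 0
  for (i in seq_len(n_t)) {
    p <- iterate_transition(p, params, tc$divisions[i])
    obs_p <- as.numeric(t(O) %*% p)
    cnt <- as.numeric(tc$counts[i, c("n_UU", "n_MU", "n_UM", "n_MM")])
    if (any(cnt > 0 & obs_p <= 0)) return(-Inf)
    # multinomial log-pmf, with 0 * log(0) treated as 0
    ll <- ll + lgamma(sum(cnt) + 1) - sum(lgamma(cnt + 1)) +
      sum(ifelse(cnt > 0, cnt * log(obs_p), 0))
  }
  ll
}

#' Fit maintenance and de novo efficiencies by maximum likelihood
#'
#' Bounded multi-start L-BFGS-B over the free parameters (by default
#' `mu` and `delta_n`; `delta_p` and `lam` are fixed at 0 and the error
#' rates at their given values). `p0` is fixed to the observed first-
#' timepoint frequencies unless `p0_free = TRUE`. With a single timepoint
#' `mu` and `delta_n` are not jointly identifiable and the fit refuses
#' unless one of them is fixed.
#'
#' @param tc a [dyad_time_course()] with >= 2 timepoints (unless
#'   constrained).
#' @param fixed named list of parameters to fix (e.g. `list(delta_n = 0)`);
#'   `e` and `c` default to fixed values below.
#' @param e,c bisulfite error rates, fixed during the fit.
#' @param n_starts number of random optimizer starts.
#' @param seed integer seed making the starts reproducible.
#' @param p0_free estimate the initial dyad distribution instead of fixing
#'   it to the first timepoint's observed frequencies.
#' @param n_boot bootstrap replicates for confidence intervals (0 = none).
#' @return list with `params` (fitted [kinetic_params()]), `loglik`,
#'   `starts` (per-start final log-likelihoods), `convergence`, and
#'   optionally `ci` (2.5/97.5% parametric-bootstrap quantiles).
#' @export
fit_kinetics <- function(tc, fixed = list(), e = 0.005, c = 0.005,
                         n_starts = 8, seed = 1, p0_free = FALSE,
                         n_boot = 0) {
  stopifnot(inherits(tc, "dyad_time_course"))
  totals <- rowSums(tc$counts[, c("n_UU", "n_MU", "n_UM", "n_MM")])
  if (any(totals <= 0)) stop("fit_kinetics: all timepoints need positive totals")
  free <- setdiff(c("mu", "delta_n"), names(fixed))
  if (length(tc$labels) < 2 && length(free) > 1)
    stop(paste("fit_kinetics: mu and delta_n are not jointly identifiable",
               "from a single timepoint; fix one of them or add timepoints"))
  p0_obs <- dyad_freqs(tc$counts[1, ])
  build <- function(theta) {
    v <- list(mu = 0, delta_n = 0, delta_p = 0, lam = 0)
    v[names(fixed)] <- fixed
    v[free] <- as.list(plogis_clip(theta[seq_along(free)]))
    p0 <- if (p0_free) softmax4(theta[length(free) + 1:3]) else p0_obs
    kinetic_params(mu = v$mu, delta_n = v$delta_n, delta_p = v$delta_p,
                   lam = v$lam, e = e, c = c, p0 = p0)
  }
  nll <- function(theta) {
    val <- -dyad_loglik(build(theta), tc)
    if (!is.finite(val)) 1e12 else val
  }
  n_par <- length(free) + if (p0_free) 3 else 0
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- matrix(stats::qlogis(runif(n_starts * n_par, 0.05, 0.95)),
                   nrow = n_starts)
  fits <- lapply(seq_len(n_starts), function(i) {
    tryCatch(optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = rep(-12, n_par), upper = rep(12, n_par)),
             error = function(err) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("fit_kinetics: no optimizer start converged")
  lls <- vapply(fits, function(f) -f$value, numeric(1))
  best <- fits[[which.max(lls)]]
  params <- build(best$par)
  out <- list(params = params, loglik = -best$value, starts = lls,
              convergence = best$convergence, free = free)
  if (n_boot > 0) {
    bs <- replicate(n_boot, {
      tc_b <- tc
      for (i in seq_along(tc$labels)) {
        p <- iterate_p_obs(params, tc, i)
        tc_b$counts[i, c("n_UU", "n_MU", "n_UM", "n_MM")] <-
          as.numeric(rmultinom(1, totals[i], p))
      }
      fb <- tryCatch(
        fit_kinetics(tc_b, fixed = fixed, e = e, c = c,
                     n_starts = max(2, n_starts %/% 2),
                     seed = sample.int(1e9, 1), p0_free = p0_free),
        error = function(err) NULL)
      if (is.null(fb)) rep(NA_real_, length(free))
      else unlist(fb$params[free])
    })
    bs <- matrix(bs, nrow = length(free))
    out$ci <- t(apply(bs, 1, quantile, c(0.025, 0.975), na.rm = TRUE))
    rownames(out$ci) <- free
  }
  out
}

iterate_p_obs <- function(params, tc, i) {
  p <- params$p0
  for (j in seq_len(i)) p <- iterate_transition(p, params, tc$divisions[j])
  as.numeric(t(observation_matrix(params$e, params$c)) %*% p)
}

plogis_clip <- function(x) 1 / (1 + exp(-pmax(pmin(x, 30), -30)))

softmax4 <- function(theta3) {
  z <- c(0, theta3)
  ez <- exp(z - max(z))
  ez / sum(ez)
}
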