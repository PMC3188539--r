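# Two-clade functional-divergence analysis.
#
# Type I model: per-site substitution counts in clades A and B are Poisson
# with means lambda_A * t_A and lambda_B * t_B. With probability 1 - theta a
# site shares one rate lambda ~ Gamma(alpha, beta) across clades; with
# probability theta the clades draw independent rates from the same gamma.
# Integrating the gamma out gives closed negative-binomial forms, so the
# mixture (theta, alpha, beta) is fit by direct numerical maximum likelihood.

# log of the shared-rate marginal: integral over one lambda
ll_shared <- function(xa, xb, ta, tb, alpha, beta) {
  lgamma(alpha + xa + xb) - lgamma(alpha) - lfactorial(xa) - lfactorial(xb) +
    xa * log(ta) + xb * log(tb) + alpha * log(beta) -
    (alpha + xa + xb) * log(beta + ta + tb)
}

# log of one independent negative-binomial margin
ll_margin <- function(x, t, alpha, beta) {
  lgamma(alpha + x) - lgamma(alpha) - lfactorial(x) +
    x * log(t) + alpha * log(beta) - (alpha + x) * log(beta + t)
}

site_loglik_parts <- function(xa, xb, ta, tb, alpha, beta) {
  list(
    l0 = ll_shared(xa, xb, ta, tb, alpha, beta),
    l1 = ll_margin(xa, ta, alpha, beta) + ll_margin(xb, tb, alpha, beta)
  )
}

mixture_negloglik <- function(par, xa, xb, ta, tb) {
  theta <- stats::plogis(par[1])
  alpha <- exp(par[2])
  beta <- exp(par[3])
  p <- site_loglik_parts(xa, xb, ta, tb, alpha, beta)
  ll <- log_add(log1p(-theta) + p$l0, log(theta) + p$l1)
  out <- -sum(ll)
  if (!is.finite(out)) return(1e10)
  out
}

#' Fit the two-clade type I rate-shift mixture
#'
#' Estimates the coefficient of type I functional divergence theta between
#' two clades: the mixture weight of sites whose substitution rate is drawn
#' independently in the two clades rather than shared. Optimisation is
#' bounded quasi-Newton over (logit theta, log alpha, log beta) from five
#' deterministic starting points; the best optimum is kept.
#'
#' @param counts A [clade_site_counts()] table covering both clades, or an
#'   equivalent tibble with columns `column`, `clade`, `raw_count`,
#'   `corrected_count`, `tree_length`.
#' @param clade_a,clade_b Clade labels; order does not matter for theta.
#' @param use `"corrected"` (default) fits on multiple-hit-corrected counts,
#'   kept real-valued (the negative-binomial forms extend analytically);
#'   `"raw"` fits on the integer minimum-change counts.
#' @return Object of class `theta_fit` with elements `theta`, `alpha`,
#'   `beta`, `log_likelihood`, `standard_error`, `kind = "typeI"`,
#'   `boundary`, `convergence`, and the per-site data needed by
#'   [type_I_posteriors()]. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
fit_type_I <- function(counts, clade_a, clade_b,
                       use = c("corrected", "raw")) {
  use <- match.arg(use)
  da <- counts[counts$clade == clade_a, ]
  db <- counts[counts$clade == clade_b, ]
  da <- da[order(da$column), ]; db <- db[order(db$column), ]
  if (!identical(da$column, db$column)) {
    stop("clades do not share the same column set", call. = FALSE)
  }
  if (nrow(da) < 30L) {
    stop("need at least 30 columns to fit the mixture", call. = FALSE)
  }
  if (use == "corrected" && !is.null(da$corrected_count)) {
    xa <- da$corrected_count
    xb <- db$corrected_count
  } else {
    xa <- as.numeric(da$raw_count)
    xb <- as.numeric(db$raw_count)
  }
  ta <- da$tree_length[1]; tb <- db$tree_length[1]
  if (ta <= 0 || tb <= 0) stop("tree lengths must be positive", call. = FALSE)

  r <- (xa + xb) / (ta + tb)
  m1 <- mean(r); v <- stats::var(r)
  alpha0 <- if (is.finite(v) && v > m1^2 / 100) max(m1^2 / v, 0.05) else 1
  beta0 <- alpha0 / max(m1, 1e-6)
  starts <- lapply(c(0.05, 0.25, 0.5, 0.75, 0.95), function(th) {
    c(stats::qlogis(th), log(alpha0), log(beta0))
  })

  # box bounds on the transformed scale keep the gamma parameters in a
  # numerically safe range (alpha, beta in about [1e-3, 1e3])
  lower <- c(-15, -7, -7)
  upper <- c(15, 7, 7)
  fits <- lapply(starts, function(p0) {
    tryCatch(
      stats::optim(pmin(pmax(p0, lower), upper), mixture_negloglik,
                   xa = xa, xb = xb, ta = ta, tb = tb,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0L) {
    stop("type I mixture fit failed to converge from every start",
         call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  theta <- stats::plogis(best$par[1])
  alpha <- exp(best$par[2]); beta <- exp(best$par[3])
  se <- tryCatch({
    H <- stats::optimHess(best$par, mixture_negloglik,
                          xa = xa, xb = xb, ta = ta, tb = tb)
    v_logit <- solve(H)[1, 1]
    # delta method: d theta / d logit = theta (1 - theta)
    sqrt(max(v_logit, 0)) * theta * (1 - theta)
  }, error = function(e) NA_real_)

  structure(
    list(
      theta = theta, alpha = alpha, beta = beta,
      log_likelihood = -best$value,
      standard_error = se,
      kind = "typeI",
      boundary = theta < 1e-3 || theta > 1 - 1e-3,
      convergence = best$convergence,
      clade_a = clade_a, clade_b = clade_b,
      column = da$column, xa = xa, xb = xb, ta = ta, tb = tb,
      rate_a = da$corrected_count %||% xa, rate_b = db$corrected_count %||% xb
    ),
    class = "theta_fit"
  )
}

#' @export
print.theta_fit <- function(x, ...) {
  cat("<theta_fit> kind=", x$kind,
      sprintf("  theta = %.3f (se %.3f)", x$theta, x$standard_error),
      if (isTRUE(x$boundary)) " [boundary]", "\n", sep = "")
  if (x$kind == "typeI") {
    cat(sprintf("  gamma shape %.3f, rate %.3f, logLik %.2f, n = %d\n",
                x$alpha, x$beta, x$log_likelihood, length(x$column)))
  }
  invisible(x)
}

#' Per-site posterior probabilities of type I divergence
#'
#' posterior_j = theta L1_j / (theta L1_j + (1 - theta) L0_j). Direction is
#' the ordered clade pair (slow, fast) by corrected rate x/t at the column.
#'
#' @param fit A [fit_type_I()] result.
#' @return Tibble with `column`, `posterior`, `slow_clade`, `fast_clade`.
#' @export
type_I_posteriors <- function(fit) {
  stopifnot(inherits(fit, "theta_fit"), fit$kind == "typeI")
  p <- site_loglik_parts(fit$xa, fit$xb, fit$ta, fit$tb, fit$alpha, fit$beta)
  num <- log(fit$theta) + p$l1
  den <- log_add(num, log1p(-fit$theta) + p$l0)
  post <- exp(num - den)
  ra <- fit$rate_a / fit$ta
  rb <- fit$rate_b / fit$tb
  a_slow <- ra <= rb
  tibble::tibble(
    column = fit$column,
    posterior = post,
    slow_clade = ifelse(a_slow, fit$clade_a, fit$clade_b),
    fast_clade = ifelse(a_slow, fit$clade_b, fit$clade_a)
  )
}

#' Classify type II sites from root states and conservation
#'
#' A column is type II iff the reconstructed states at the two clade roots
#' fall in different radical property groups ([radical_groups()]) and the
#' corrected within-clade counts are at most `conservation_ceiling` in both
#' clades (the change is fixed, not ongoing variation). The type II
#' coefficient is the proportion of type II columns among columns conserved
#' in both clades -- a deterministic proportion estimator, reported with a
#' binomial standard error and flagged as a methodological simplification.
#'
#' @param anc_a,anc_b [reconstruct_ancestral_states()] results for the two
#'   clades.
#' @param counts A [clade_site_counts()] table covering both clades.
#' @param clade_a,clade_b Clade labels matching `counts`.
#' @param conservation_ceiling Maximum corrected count still treated as
#'   conserved (default 0.5).
#' @return List with `calls` (tibble: `column`, `type_ii`, `conserved_both`,
#'   `group_a`, `group_b`) and `theta` (a `theta_fit` of kind `"typeII"`).
#' @export
classify_type_II <- function(anc_a, anc_b, counts, clade_a, clade_b,
                             conservation_ceiling = 0.5) {
  da <- counts[counts$clade == clade_a, ]
  db <- counts[counts$clade == clade_b, ]
  da <- da[order(da$column), ]; db <- db[order(db$column), ]
  root_a <- anc_a$root_state[da$column]
  root_b <- anc_b$root_state[db$column]
  ga <- radical_group_of(root_a)
  gb <- radical_group_of(root_b)
  skip <- is.na(ga) | is.na(gb)
  if (any(skip)) {
    warning(sum(skip), " column(s) skipped: missing root state",
            call. = FALSE)
  }
  conserved <- da$corrected_count <= conservation_ceiling &
    db$corrected_count <= conservation_ceiling
  type_ii <- !skip & conserved & ga != gb
  n_cons <- sum(conserved & !skip)
  theta2 <- if (n_cons > 0) sum(type_ii) / n_cons else 0
  theta <- structure(
    list(
      theta = theta2, alpha = NA_real_, beta = NA_real_,
      log_likelihood = NA_real_,
      standard_error = if (n_cons > 0) {
        sqrt(theta2 * (1 - theta2) / n_cons)
      } else NA_real_,
      kind = "typeII", boundary = FALSE, convergence = 0L,
      clade_a = clade_a, clade_b = clade_b,
      n_conserved = n_cons
    ),
    class = "theta_fit"
  )
  list(
    calls = tibble::tibble(
      column = da$column, type_ii = type_ii, conserved_both = conserved,
      group_a = ga, group_b = gb
    ),
    theta = theta
  )
}

#' Classify each column as type 0, I, II or none for a clade pair
#'
#' Type II takes precedence over type I when both trigger (a radical fixed
#' difference is the stronger statement). Type 0 requires zero observed
#' (raw) substitutions in both clades and an identical consensus residue;
#' type I requires posterior above `cutoff`.
#'
#' @param aln An `msa` object.
#' @param partition Clade map tibble.
#' @param posteriors A [type_I_posteriors()] table.
#' @param typeii A [classify_type_II()] result.
#' @param counts A [clade_site_counts()] table.
#' @param clade_a,clade_b The clade pair.
#' @param cutoff Posterior cutoff for type I calls (default 0.90).
#' @return Tibble with `column`, `clade_a`, `clade_b`, `class` (factor:
#'   type0/typeI/typeII/none), `posterior`, `slow_clade`, `fast_clade`.
#' @export
classify_sites <- function(aln, partition, posteriors, typeii, counts,
                           clade_a, clade_b, cutoff = 0.90) {
  stopifnot(cutoff > 0.5, cutoff < 1)
  da <- counts[counts$clade == clade_a, ]
  db <- counts[counts$clade == clade_b, ]
  da <- da[order(da$column), ]; db <- db[order(db$column), ]
  post <- posteriors[order(posteriors$column), ]
  t2 <- typeii$calls[order(typeii$calls$column), ]

  cons_a <- consensus_residues(aln, clade_leaves(partition, clade_a))
  cons_b <- consensus_residues(aln, clade_leaves(partition, clade_b))
  zero_both <- da$raw_count == 0 & db$raw_count == 0
  same_cons <- !is.na(cons_a$residue[da$column]) &
    !is.na(cons_b$residue[db$column]) &
    cons_a$residue[da$column] == cons_b$residue[db$column]

  cls <- rep("none", nrow(da))
  cls[post$posterior > cutoff] <- "typeI"
  cls[t2$type_ii] <- "typeII"
  cls[cls == "none" & zero_both & same_cons] <- "type0"

  tibble::tibble(
    column = da$column,
    clade_a = clade_a, clade_b = clade_b,
    class = factor(cls, levels = c("type0", "typeI", "typeII", "none")),
    posterior = post$posterior,
    slow_clade = ifelse(cls == "typeI", post$slow_clade, NA_character_),
    fast_clade = ifelse(cls == "typeI", post$fast_clade, NA_character_)
  )
}

# Per-column consensus residue and frequency within a leaf set.
consensus_residues <- function(aln, leaves) {
  m <- unclass(aln)[leaves, , drop = FALSE]
  res <- apply(m, 2, function(col) {
    obs <- col[col %in% AA20]
    if (length(obs) == 0L) {
      return(c(NA_character_, "0", as.character(length(col))))
    }
    tab <- sort(table(obs), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    c(sort(top)[1], as.character(tab[1]), as.character(sum(!(col %in% AA20))))
  })
  n <- ncol(m)
  tibble::tibble(
    column = seq_len(ncol(aln)),
    residue = res[1, ],
    frequency = as.numeric(res[2, ]) / nrow(m),
    gap_fraction = as.numeric(res[3, ]) / nrow(m)
  )
}

#' Pairwise functional-divergence table over all clades
#'
#' Fits the type I mixture and the type II proportion for every unordered
#' clade pair. Failed pairs are kept with `NA` estimates and the error text.
#'
#' @param aln An `msa` object.
#' @param trees Named list of clade trees.
#' @param partition Clade map tibble.
#' @param counts Optional precomputed [clade_site_counts()] table.
#' @param model,correction Passed to [clade_site_counts()] when `counts` is
#'   not supplied.
#' @param conservation_ceiling Passed to [classify_type_II()].
#' @return Tibble with one row per unordered pair: `clade_a`, `clade_b`,
#'   `theta_type1`, `se_type1`, `theta_type2`, `se_type2`, `error`.
#' @export
pairwise_theta_table <- function(aln, trees, partition, counts = NULL,
                                 model = "marginal-ml",
                                 correction = "poisson-ml",
                                 conservation_ceiling = 0.5) {
  clades <- sort(unique(partition$clade))
  if (length(clades) < 2L) stop("need at least two clades", call. = FALSE)
  if (is.null(counts)) {
    counts <- clade_site_counts(aln, trees, partition, model = model,
                                correction = correction)
  }
  anc <- lapply(stats::setNames(clades, clades), function(cl) {
    reconstruct_ancestral_states(aln, trees[[cl]], model = model)
  })
  pairs <- utils::combn(clades, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    out <- tibble::tibble(clade_a = a, clade_b = b,
                          theta_type1 = NA_real_, se_type1 = NA_real_,
                          theta_type2 = NA_real_, se_type2 = NA_real_,
                          error = NA_character_)
    tryCatch({
      f1 <- fit_type_I(counts, a, b)
      f2 <- classify_type_II(anc[[a]], anc[[b]], counts, a, b,
                             conservation_ceiling = conservation_ceiling)
      out$theta_type1 <- f1$theta
      out$se_type1 <- f1$standard_error
      out$theta_type2 <- f2$theta$theta
      out$se_type2 <- f2$theta$standard_error
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  dplyr::bind_rows(rows)
}

#' Arrange the pairwise table as a matrix
#'
#' Type I coefficients fill the upper triangle and type II the lower
#' triangle; the diagonal is empty (`NA`).
#'
#' @param theta_table A [pairwise_theta_table()] result.
#' @return Numeric matrix with clade labels on both dimensions.
#' @export
theta_matrix <- function(theta_table) {
  clades <- sort(unique(c(theta_table$clade_a, theta_table$clade_b)))
  m <- matrix(NA_real_, length(clades), length(clades),
              dimnames = list(clades, clades))
  for (i in seq_len(nrow(theta_table))) {
    a <- theta_table$clade_a[i]; b <- theta_table$clade_b[i]
    lo <- min(a, b); hi <- max(a, b)
    m[lo, hi] <- theta_table$theta_type1[i]
    m[hi, lo] <- theta_table$theta_type2[i]
  }
  m
}
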