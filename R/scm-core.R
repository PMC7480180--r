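#' Predictor specification for synthetic-control matching
#'
#' Declares which panel columns enter the matching problem. Covariates are
#' matched as pre-intervention means; outcomes are matched as full
#' pre-intervention monthly paths. With `standardize = TRUE` (default) every
#' predictor row is divided by its donor-pool standard deviation so that no
#' predictor dominates through scale alone.
#'
#' @param covariates character vector of covariate column names (matched as
#'   pre-period means). Emergency length of stay and list size are included
#'   by default.
#' @param outcomes character vector of outcome series names (matched as full
#'   pre-period paths); must be non-empty.
#' @param standardize logical; scale predictor rows by donor-pool SD.
#' @return an object of class `predictor_spec`.
#' @export
predictor_spec <- function(covariates = c("list_size", "em_los", COVARIATE_COLS),
                           outcomes = OUTCOME_COLS,
                           standardize = TRUE) {
  if (!length(outcomes)) stopf("at least one outcome series is required")
  structure(list(covariates = covariates, outcomes = outcomes,
                 standardize = isTRUE(standardize)),
            class = "predictor_spec")
}

# months x ids matrix of one panel column.
path_matrix <- function(panel, ids, months, col) {
  sub <- panel[panel$practice_id %in% ids & panel$month_index %in% months, ]
  m <- matrix(NA_real_, length(months), length(ids),
              dimnames = list(months, ids))
  m[cbind(match(sub$month_index, months), match(sub$practice_id, ids))] <-
    sub[[col]]
  if (anyNA(m)) stopf("panel is missing rows for column %s", col)
  m
}

#' Assemble synthetic-control matching matrices
#'
#' Builds the treated predictor vector `X1` (covariate pre-period means
#' stacked over the outcome pre-period paths), the matching donor matrix
#' `X0` (one column per donor), and the outcome-only blocks `Z1`/`Z0` used
#' by the outer fit criterion.
#'
#' @param panel monthly panel data.frame.
#' @param pool a [build_donor_pool()] result.
#' @param spec a [predictor_spec()].
#' @param pre_window integer vector of pre-intervention month indices
#'   (ending the month before the join month).
#' @return list with `X1`, `X0`, `Z1`, `Z0`, `z_outcome` (outcome label per
#'   Z row), `dropped` (names of zero-variance predictor rows removed when
#'   standardizing) and `scale` (the row scaling applied).
#' @export
assemble_matrices <- function(panel, pool, spec, pre_window) {
  if (!length(pre_window)) stopf("pre_window must be non-empty")
  missing <- setdiff(c(spec$covariates, spec$outcomes), names(panel))
  if (length(missing))
    stopf("panel lacks predictor column(s): %s", paste(missing, collapse = ", "))
  ids <- c(pool$treated_id, pool$donor_ids)

  blocks1 <- list(); blocks0 <- list()
  for (cv in spec$covariates) {
    m <- path_matrix(panel, ids, pre_window, cv)
    mu <- colMeans(m)
    blocks1[[cv]] <- stats::setNames(mu[1], cv)
    blocks0[[cv]] <- matrix(mu[-1], 1, dimnames = list(cv, pool$donor_ids))
  }
  z1 <- c(); z0 <- NULL; z_outcome <- c()
  for (oc in spec$outcomes) {
    m <- path_matrix(panel, ids, pre_window, oc)
    rn <- sprintf("%s.m%d", oc, pre_window)
    blocks1[[oc]] <- stats::setNames(m[, 1], rn)
    b0 <- m[, -1, drop = FALSE]; rownames(b0) <- rn
    blocks0[[oc]] <- b0
    if (max(apply(b0, 1, stats::sd)) == 0 && ncol(b0) > 1)
      stopf("outcome %s has zero variance across all donors in the pre-period", oc)
    z1 <- c(z1, blocks1[[oc]]); z0 <- rbind(z0, b0)
    z_outcome <- c(z_outcome, rep(oc, length(pre_window)))
  }
  X1 <- unlist(blocks1, use.names = FALSE)
  names(X1) <- unlist(lapply(blocks1, names))
  X0 <- do.call(rbind, blocks0)

  dropped <- character(0)
  scale <- rep(1, length(X1)); names(scale) <- names(X1)
  if (spec$standardize) {
    s <- apply(X0, 1, stats::sd)
    zero <- s == 0 | !is.finite(s)
    if (any(zero)) {
      dropped <- names(X1)[zero]
      warnf("dropping zero-variance predictor row(s): %s",
            paste(dropped, collapse = ", "))
      X1 <- X1[!zero]; X0 <- X0[!zero, , drop = FALSE]; s <- s[!zero]
    }
    X1 <- X1 / s; X0 <- X0 / s
    scale <- s
  }
  list(X1 = X1, X0 = X0, Z1 = z1, Z0 = z0, z_outcome = z_outcome,
       x_is_outcome = grepl("\\.m\\d+$", names(X1)),
       dropped = dropped, scale = scale)
}

#' Solve the inner synthetic-control weight problem
#'
#' Finds donor weights `W` minimizing
#' \eqn{(X_1 - X_0 W)^\top \mathrm{diag}(V) (X_1 - X_0 W)} subject to
#' \eqn{W \ge 0,\ \sum W = 1}, as an exact convex quadratic programme
#' (dual active-set method). A relative ridge of 1e-8 on the Hessian
#' diagonal guarantees positive definiteness when donors outnumber
#' predictors.
#'
#' @param X1 treated predictor vector.
#' @param X0 predictor-by-donor matrix.
#' @param V non-negative predictor weights summing to 1.
#' @return weight vector `W` on the simplex, named by donor.
#' @export
solve_inner_weights <- function(X1, X0, V) {
  if (any(V < 0)) stopf("V must be non-negative")
  if (abs(sum(V) - 1) > 1e-6) stopf("V must sum to 1")
  n <- ncol(X0)
  if (n == 1L) return(stats::setNames(1, colnames(X0)))
  XV <- X0 * V
  D <- 2 * crossprod(X0, XV)
  D <- D + diag(1e-8 * max(1, mean(diag(D))), n)
  d <- 2 * as.vector(crossprod(X0, V * X1))
  A <- cbind(rep(1, n), diag(n))
  sol <- tryCatch(
    quadprog::solve.QP(D, d, A, c(1, rep(0, n)), meq = 1),
    error = function(e) stopf("inner QP failed: %s", conditionMessage(e))
  )
  w <- pmax(sol$solution, 0)
  w <- w / sum(w)
  stats::setNames(w, colnames(X0))
}

inner_objective <- function(w, X1, X0, V) {
  r <- X1 - as.vector(X0 %*% w)
  sum(V * r^2)
}

# Mean squared pre-period prediction error of the outcome block.
z_mspe <- function(w, Z1, Z0) mean((Z1 - as.vector(Z0 %*% w))^2)

#' Fit a multivariate synthetic control for one treated practice
#'
#' Nested optimisation in the standard synthetic-control formulation: the
#' inner problem solves for donor weights `W(V)` given diagonal predictor
#' weights `V` (exact QP); the outer problem searches the `V` simplex to
#' minimise the pre-period outcome mean squared prediction error of `W(V)`.
#' The outer search runs Nelder-Mead in softmax coordinates from the equal-V
#' start plus `multistarts` random starts with fixed internal seeds, so the
#' fit is deterministic. The raw equal-V solution is always a candidate, so
#' the fitted objective is never worse than the equal-V baseline. Ties are
#' broken by lowest objective, then lexicographically smallest `W`.
#'
#' @param panel monthly panel data.frame.
#' @param pool a [build_donor_pool()] result.
#' @param spec a [predictor_spec()].
#' @param pre_window integer vector of pre-intervention months.
#' @param optimize_v if `FALSE`, skip the Nelder-Mead outer search and take
#'   the better of the equal-V and outcome-only-V solutions (much faster;
#'   used for large simulation studies).
#' @param multistarts number of random outer starts in addition to equal-V.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param mspe_cap optional warning threshold on the overall pre-period MSPE.
#' @return an object of class `scm_fit`: `treated_id`, `donor_ids`, `W`,
#'   `V`, `pre_mspe` (per outcome), `objective` (overall pre-period MSPE),
#'   `converged`, `pre_window`, `spec`.
#' @export
fit_synthetic_control <- function(panel, pool, spec, pre_window,
                                  optimize_v = TRUE, multistarts = 5,
                                  maxit = 200, mspe_cap = NULL) {
  mats <- assemble_matrices(panel, pool, spec, pre_window)
  p <- length(mats$X1)
  eq_v <- rep(1 / p, p)

  candidates <- list()
  add_candidate <- function(v, converged = TRUE) {
    w <- solve_inner_weights(mats$X1, mats$X0, v)
    candidates[[length(candidates) + 1L]] <<-
      list(V = v, W = w, obj = z_mspe(w, mats$Z1, mats$Z0),
           converged = converged)
  }
  add_candidate(eq_v)

  # Dependent-variable-only predictor weights: concentrating V on the
  # outcome rows (proportional to their squared scaling) makes the inner
  # fit minimise the raw outcome MSPE directly, so the nested optimum is
  # never worse than a pure outcome-path fit.
  z_v <- NULL
  if (any(mats$x_is_outcome)) {
    z_v <- ifelse(mats$x_is_outcome, mats$scale^2, 0)
    z_v <- z_v / sum(z_v)
    add_candidate(z_v)
  }

  if (optimize_v && p > 1L && ncol(mats$X0) > 1L) {
    outer_obj <- function(theta) {
      v <- exp(theta - max(theta)); v <- v / sum(v)
      w <- solve_inner_weights(mats$X1, mats$X0, v)
      z_mspe(w, mats$Z1, mats$Z0)
    }
    starts <- c(list(rep(0, p)),
                if (!is.null(z_v)) list(log(pmax(z_v, 1e-12))),
                lapply(seq_len(multistarts), function(k)
                  with_seed(90000 + k, stats::rnorm(p))))
    for (th0 in starts) {
      opt <- stats::optim(th0, outer_obj, method = "Nelder-Mead",
                          control = list(maxit = maxit))
      v <- exp(opt$par - max(opt$par)); v <- v / sum(v)
      add_candidate(v, converged = opt$convergence == 0)
    }
  }

  objs <- vapply(candidates, `[[`, numeric(1), "obj")
  best_obj <- min(objs)
  tied <- which(objs <= best_obj + 1e-12)
  if (length(tied) > 1L) {
    ws <- lapply(candidates[tied], `[[`, "W")
    ord <- do.call(order, as.data.frame(t(vapply(ws, as.numeric,
                                                 numeric(length(ws[[1]]))))))
    best <- candidates[[tied[ord[1]]]]
  } else best <- candidates[[tied]]

  per_outcome <- vapply(unique(mats$z_outcome), function(oc) {
    i <- mats$z_outcome == oc
    mean((mats$Z1[i] - as.vector(mats$Z0[i, , drop = FALSE] %*% best$W))^2)
  }, numeric(1))

  if (!is.null(mspe_cap) && best$obj > mspe_cap)
    warnf("pre-period MSPE %.4g exceeds cap %.4g for %s",
          best$obj, mspe_cap, pool$treated_id)

  structure(list(treated_id = pool$treated_id, donor_ids = pool$donor_ids,
                 W = best$W, V = stats::setNames(best$V, names(mats$X1)),
                 pre_mspe = per_outcome, objective = best$obj,
                 converged = best$converged, pre_window = pre_window,
                 spec = spec),
            class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Synthetic control fit for %s (%d donors)\n",
              x$treated_id, length(x$donor_ids)))
  cat(sprintf("  pre-period MSPE: %s (overall %.4g)\n",
              paste(sprintf("%s %.4g", names(x$pre_mspe), x$pre_mspe),
                    collapse = ", "), x$objective))
  w <- sort(x$W[x$W > 1e-3], decreasing = TRUE)
  cat("  donor weights > 0.001:\n")
  for (i in seq_along(w))
    cat(sprintf("    %s: %.*f\n", names(w)[i], digits, w[i]))
  invisible(x)
}

#' Synthetic-control outcome paths
#'
#' The synthetic series for each outcome over `months` is the fitted convex
#' combination of the donor paths, `Z0(months) %*% W`.
#'
#' @param fit an `scm_fit`.
#' @param panel monthly panel data.frame.
#' @param months integer month indices to predict.
#' @return data.frame with columns `outcome`, `month_index`, `synthetic`,
#'   `treated`.
#' @export
predict_outcomes <- function(fit, panel, months) {
  rng <- range(panel$month_index)
  if (min(months) < rng[1] || max(months) > rng[2])
    stopf("months outside panel range [%d, %d]", rng[1], rng[2])
  out <- lapply(fit$spec$outcomes, function(oc) {
    m <- path_matrix(panel, c(fit$treated_id, fit$donor_ids), months, oc)
    data.frame(outcome = oc, month_index = months,
               synthetic = as.vector(m[, -1, drop = FALSE] %*% fit$W),
               treated = m[, 1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
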