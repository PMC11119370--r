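## Network controllability of a discrete-time linear system built from a
## functional-connectivity matrix.
##
## The brain is modelled as x(t+1) = A x(t) + B u(t), where A is the
## (stabilized) FC adjacency and B selects the input node. For a single
## input at node k (B_k = indicator e_k), the controllability Gramian
##
##     W_k = sum_{tau >= 0} A^tau B_k B_k' (A')^tau
##
## converges whenever A is Schur stable and solves the discrete-time
## Lyapunov equation W = A W A' + B_k B_k'. Average controllability of
## node k is trace(W_k): large values mean input at k can push the system
## into many nearby states with little energy. The tau = 0 term alone
## contributes trace(B_k B_k') = 1, hence every value is >= 1.

#' Stabilize an adjacency matrix into a discrete-time linear system
#'
#' Divides the matrix by `c + sigma_max` (largest singular value), which
#' guarantees the largest singular value of the result is
#' `sigma_max / (c + sigma_max) < 1`, i.e. Schur stability, for any input.
#'
#' @param fc a `connectivity_matrix`, or a plain square numeric matrix.
#' @param c positive normalization offset (default 1).
#' @return a `linear_system`: list with `a_stable`,
#'   `normalization_constant` (the scalar divisor applied), `n_regions`,
#'   `region_labels`, plus the subject metadata when available.
#' @export
#' @examples
#' m <- matrix(c(0, .5, .5, 0), 2)
#' stabilize_adjacency(m)$a_stable
stabilize_adjacency <- function(fc, c = 1) {
  if (inherits(fc, "connectivity_matrix")) {
    m <- fc$values
    labels <- fc$region_labels
    subject_id <- fc$subject_id
    group_label <- fc$group_label
  } else {
    m <- fc
    labels <- colnames(m) %||% default_region_labels(ncol(m))
    subject_id <- NA_character_
    group_label <- NA_integer_
  }
  check_square_finite(m, "adjacency")
  if (c <= 0) stop_invalid("normalization offset c must be > 0")
  sigma_max <- if (is_symmetric_tol(m, 1e-10)) {
    max(abs(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values))
  } else {
    svd(m, nu = 0, nv = 0)$d[1]
  }
  divisor <- c + sigma_max
  structure(list(a_stable = m / divisor,
                 normalization_constant = divisor,
                 n_regions = ncol(m),
                 region_labels = labels,
                 subject_id = subject_id,
                 group_label = group_label),
            class = "linear_system")
}

spectral_norm <- function(m) svd(m, nu = 0, nv = 0)$d[1]

check_stable <- function(model) {
  stopifnot(inherits(model, "linear_system"))
  if (spectral_norm(model$a_stable) >= 1)
    stop("system matrix is not Schur stable (largest singular value >= 1)",
         call. = FALSE)
  invisible(model)
}

#' Single-node controllability Gramian
#'
#' Solves the discrete-time Lyapunov equation `W = A W A' + e_k e_k'`
#' (the closed form of the infinite Gramian series) by a doubling
#' iteration: `W <- W + A_j W A_j'`, `A_j <- A_j^2`, which converges
#' geometrically for Schur-stable A.
#'
#' @param model a `linear_system` from [stabilize_adjacency()].
#' @param node 1-based input-node index.
#' @param tol stop once the squared spectral norm of the doubled matrix
#'   falls below this.
#' @return a `ctrl_gramian`: list with `node`, `selector`, `w`
#'   (symmetric PSD matrix) and `residual` (Frobenius norm of the
#'   Lyapunov defect).
#' @export
node_gramian <- function(model, node, tol = 1e-14) {
  check_stable(model)
  n <- model$n_regions
  node <- check_count(node, "node")
  if (node > n) stop_invalid("node %d out of range [1, %d]", node, n)
  a <- model$a_stable
  w <- matrix(0, n, n)
  w[node, node] <- 1
  ak <- a
  repeat {
    w <- w + ak %*% w %*% t(ak)
    ak <- ak %*% ak
    if (spectral_norm(ak)^2 < tol) break
  }
  w <- (w + t(w)) / 2
  bbt <- matrix(0, n, n)
  bbt[node, node] <- 1
  residual <- norm(a %*% w %*% t(a) + bbt - w, "F")
  selector <- numeric(n)
  selector[node] <- 1
  structure(list(node = node, selector = selector, w = w,
                 residual = residual),
            class = "ctrl_gramian")
}

#' Truncated Gramian series (test oracle)
#'
#' Direct evaluation of `sum_{tau=0}^{n_terms-1} A^tau e_k e_k' (A')^tau`
#' by repeated multiplication. Kept as an independent check of the
#' Lyapunov solution; converges to it as `n_terms` grows.
#'
#' @inheritParams node_gramian
#' @param n_terms number of series terms (>= 1).
#' @return the partial-sum matrix.
#' @export
truncated_sum_oracle <- function(model, node, n_terms) {
  stopifnot(inherits(model, "linear_system"))
  n_terms <- check_count(n_terms, "n_terms")
  n <- model$n_regions
  a <- model$a_stable
  term <- matrix(0, n, n)
  term[node, node] <- 1
  acc <- term
  apow <- diag(n)
  for (tau in seq_len(n_terms - 1)) {
    apow <- a %*% apow
    acc <- acc + apow %*% term %*% t(apow)
  }
  acc
}

#' Per-region average-controllability profile
#'
#' `trace(W_k)` for every region k. For symmetric A (the FC case) this
#' uses the eigendecomposition `A = V L V'`, under which
#' `trace(W_k) = sum_i V[k,i]^2 / (1 - lambda_i^2)` — one decomposition
#' per subject instead of one Lyapunov solve per region. Non-symmetric
#' systems fall back to per-node [node_gramian()] solves.
#'
#' @param model a `linear_system`.
#' @param subject_id,group_label metadata carried into the result
#'   (defaults taken from the model).
#' @return a `ctrl_profile`: list with `values` (named numeric vector,
#'   every entry >= 1), `region_labels`, `subject_id`, `group_label`.
#' @export
average_controllability_profile <- function(model,
                                            subject_id = model$subject_id,
                                            group_label = model$group_label) {
  check_stable(model)
  a <- model$a_stable
  if (is_symmetric_tol(a, 1e-10)) {
    e <- eigen((a + t(a)) / 2, symmetric = TRUE)
    vals <- as.numeric((e$vectors^2) %*% (1 / (1 - e$values^2)))
  } else {
    vals <- vapply(seq_len(model$n_regions),
                   function(k) sum(diag(node_gramian(model, k)$w)),
                   numeric(1))
  }
  names(vals) <- model$region_labels
  structure(list(subject_id = subject_id,
                 group_label = group_label,
                 values = vals,
                 region_labels = model$region_labels),
            class = "ctrl_profile")
}

#' Average-controllability profiles for a whole cohort
#'
#' Convenience wrapper: stabilize each subject's FC matrix and compute
#' the profile, returning a cohort-level container.
#'
#' @param fcs list of `connectivity_matrix`.
#' @param c normalization offset, see [stabilize_adjacency()].
#' @return a `ctrl_profile_set`: list with `values` (subjects x regions
#'   matrix), `subject_id`, `group_label`, `region_labels`.
#' @export
profiles_for_cohort <- function(fcs, c = 1) {
  profs <- lapply(fcs, function(fc)
    average_controllability_profile(stabilize_adjacency(fc, c = c)))
  labels <- profs[[1]]$region_labels
  for (p in profs)
    if (!identical(p$region_labels, labels))
      stop_invalid("region labels differ across subjects (first mismatch: subject %s)",
                   p$subject_id)
  structure(list(values = do.call(rbind, lapply(profs, `[[`, "values")),
                 subject_id = vapply(profs, `[[`, character(1), "subject_id"),
                 group_label = vapply(profs, `[[`, integer(1), "group_label"),
                 region_labels = labels),
            class = "ctrl_profile_set")
}

#' Write a cohort's controllability profiles as one TSV
#' @param profiles a `ctrl_profile_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(subject_id = profiles$subject_id,
                   group_label = profiles$group_label,
                   profiles$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort profile TSV written by [write_profiles()]
#' @param path profile TSV.
#' @return a `ctrl_profile_set`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "group_label")),
                       drop = FALSE])
  structure(list(values = vals,
                 subject_id = as.character(df$subject_id),
                 group_label = as.integer(df$group_label),
                 region_labels = colnames(vals)),
            class = "ctrl_profile_set")
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("Discrete-time linear system: %d regions, divisor %.4f, sigma_max(A) = %.4f\n",
              x$n_regions, x$normalization_constant, spectral_norm(x$a_stable)))
  invisible(x)
}

#' @export
print.ctrl_profile <- function(x, ...) {
  cat(sprintf("Average-controllability profile: subject %s (group %s), %d regions, range [%.4f, %.4f]\n",
              x$subject_id, x$group_label, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.ctrl_profile_set <- function(x, ...) {
  cat(sprintf("Controllability profiles: %d subjects x %d regions (groups: %d/%d), value range [%.4f, %.4f]\n",
              nrow(x$values), ncol(x$values),
              sum(x$group_label == 0), sum(x$group_label == 1),
              min(x$values), max(x$values)))
  invisible(x)
}
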