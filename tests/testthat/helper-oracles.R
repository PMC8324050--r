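# Shared toy models and independent brute-force oracles.
#
# The oracles deliberately avoid the package's LP and double-description
# code paths: LPs are solved by basic-solution enumeration (or
# pracma::linprog), and extreme rays by exhaustive support enumeration
# over the nullspace.

toy_chain <- function(cap = 10) {
  newMetabolicModel("chain",
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = cap, kind = "exchange"),
      reaction("cnv", c(A = -1, B = 1), lower = 0),
      reaction("out", c(B = -1), lower = 0, kind = "exchange")))
}

# two parallel routes of equal length from A to B
toy_parallel <- function(cap = 10) {
  newMetabolicModel("parallel",
    metabolites = data.frame(id = c("A", "M1", "M2", "B")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = cap, kind = "exchange"),
      reaction("p1a", c(A = -1, M1 = 1), lower = 0),
      reaction("p1b", c(M1 = -1, B = 1), lower = 0),
      reaction("p2a", c(A = -1, M2 = 1), lower = 0),
      reaction("p2b", c(M2 = -1, B = 1), lower = 0),
      reaction("out", c(B = -1), lower = 0, kind = "exchange")))
}

# a linear path plus a 2-reaction stoichiometrically balanced cycle
toy_with_cycle <- function(cap = 5) {
  newMetabolicModel("cycle",
    metabolites = data.frame(id = c("A", "B", "X", "Y")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = cap, kind = "exchange"),
      reaction("cnv", c(A = -1, B = 1), lower = 0),
      reaction("out", c(B = -1), lower = 0, kind = "exchange"),
      reaction("loop_f", c(X = -1, Y = 1), lower = 0, upper = 1000),
      reaction("loop_b", c(Y = -1, X = 1), lower = 0, upper = 1000)))
}

# Brute-force LP oracle: maximize c'x s.t. A x = b, lb <= x <= ub, by
# enumerating basic solutions. Returns NA if no nondegenerate basis
# exists (rank-deficient A); callers skip those cases.
brute_lp <- function(A, b, lb, ub, cc) {
  n <- ncol(A); m <- nrow(A); best <- -Inf
  if (m == 0) {
    x <- ifelse(cc > 0, ub, lb)
    return(sum(cc * x))
  }
  combs <- utils::combn(n, m)
  nb_choices <- expand.grid(rep(list(c(1, 2)), n - m))
  found <- FALSE
  for (ci in seq_len(ncol(combs))) {
    Bset <- combs[, ci]; Nset <- setdiff(seq_len(n), Bset)
    Bm <- A[, Bset, drop = FALSE]
    if (abs(det(Bm)) < 1e-9) next
    for (gi in seq_len(nrow(nb_choices))) {
      xn <- ifelse(unlist(nb_choices[gi, ]) == 1, lb[Nset], ub[Nset])
      if (any(!is.finite(xn))) next
      xb <- solve(Bm, b - A[, Nset, drop = FALSE] %*% xn)
      x <- numeric(n); x[Nset] <- xn; x[Bset] <- xb
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8)) {
        found <- TRUE
        best <- max(best, sum(cc * x))
      }
    }
  }
  if (!found) NA_real_ else best
}

# Brute-force extreme rays of {v >= 0, A v = 0} by support enumeration:
# the support of an extreme ray satisfies rank(A[, J]) = |J| - 1 with a
# one-dimensional nullspace of constant sign. Integer-normalized columns.
brute_flux_rays <- function(A) {
  n <- ncol(A)
  rays <- list()
  for (size in seq_len(n)) {
    for (J in utils::combn(n, size, simplify = FALSE)) {
      M <- A[, J, drop = FALSE]
      qrM <- qr(M)
      if (qrM$rank != length(J) - 1 && !(length(J) == 1 && qrM$rank == 0))
        next
      ns <- if (length(J) == 1) matrix(1, 1, 1) else {
        nsp <- MASS::Null(t(M))
        if (ncol(nsp) != 1) next
        nsp
      }
      v <- as.vector(ns)
      if (max(abs(v)) < 1e-12) next
      if (all(v >= -1e-10)) v <- v else if (all(v <= 1e-10)) v <- -v
      else next
      if (any(abs(v) < 1e-10)) next  # support must be exactly J
      full <- numeric(n)
      full[J] <- v
      # integer-normalize for comparison
      full <- full / min(abs(full[J]))
      key <- paste(round(full, 8), collapse = ",")
      rays[[key]] <- full
    }
  }
  if (!length(rays)) return(matrix(0, n, 0))
  do.call(cbind, rays)
}

# Extreme rays of the conversion cone by brute force: enumerate the flux
# cone (reversible reactions split, direction constraints as extra slack
# columns), project onto the tracked metabolites, deduplicate, and
# reduce to extreme rays with pracma::linprog as the independent LP.
brute_ecms <- function(model, config) {
  met <- model@metabolites
  rxn <- model@reactions
  keep <- !(rxn$kind %in% c("exchange", "demand", "sink"))
  S <- as.matrix(model@stoichiometry[, keep, drop = FALSE])
  lb <- rxn$lower[keep]; ub <- rxn$upper[keep]
  cols <- list()
  for (j in seq_len(ncol(S))) {
    if (ub[j] > 0) cols[[length(cols) + 1]] <- S[, j]
    if (lb[j] < 0) cols[[length(cols) + 1]] <- -S[, j]
  }
  Ssplit <- do.call(cbind, cols)
  tracked <- c(config$inputs, config$outputs, config$free)
  int_rows <- setdiff(met$id, c(tracked, config$hidden))
  Sint <- Ssplit[int_rows, , drop = FALSE]
  Sext <- Ssplit[tracked, , drop = FALSE]
  # direction constraints via slack columns: a'v - s = 0, s >= 0
  dir_rows <- NULL
  for (id in config$inputs) dir_rows <- rbind(dir_rows, -Ssplit[id, ])
  for (id in config$outputs) dir_rows <- rbind(dir_rows, Ssplit[id, ])
  nslack <- if (is.null(dir_rows)) 0 else nrow(dir_rows)
  A <- rbind(cbind(Sint, matrix(0, nrow(Sint), nslack)),
             if (nslack) cbind(dir_rows, -diag(nslack)))
  rays <- brute_flux_rays(A)
  if (ncol(rays) == 0) return(matrix(0, 0, length(tracked),
                                     dimnames = list(NULL, tracked)))
  conv <- Sext %*% rays[seq_len(ncol(Ssplit)), , drop = FALSE]
  conv <- conv[, colSums(abs(conv)) > 1e-9, drop = FALSE]
  if (ncol(conv) == 0) return(matrix(0, 0, length(tracked),
                                     dimnames = list(NULL, tracked)))
  norm <- apply(conv, 2, function(v) v / max(abs(v)))
  norm <- matrix(norm, nrow = nrow(conv))
  keyed <- unique(lapply(seq_len(ncol(norm)), function(i) round(norm[, i], 8)))
  G <- do.call(cbind, keyed)
  # drop generators that are conic combinations of the others
  repeat {
    dropped <- FALSE
    for (i in seq_len(ncol(G))) {
      if (ncol(G) <= 1) break
      others <- G[, -i, drop = FALSE]
      # feasibility: others %*% lambda = G[, i], lambda >= 0
      p <- tryCatch(
        pracma::linprog(rep(0, ncol(others)), Aeq = others,
                        beq = G[, i], maxiter = 500),
        error = function(e) NULL)
      feasible <- !is.null(p) && p$errno == 1 &&
        max(abs(others %*% p$x - G[, i])) < 1e-6
      if (feasible) {
        G <- G[, -i, drop = FALSE]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  out <- t(G)
  colnames(out) <- tracked
  out
}

# order-insensitive comparison of two conversion matrices up to positive
# scaling of each row
expect_same_conversions <- function(got, want, tol = 1e-7) {
  norm_rows <- function(M) {
    if (nrow(M) == 0) return(character())
    sort(apply(M, 1, function(v) {
      v <- v / max(abs(v))
      paste(round(v, 6), collapse = ",")
    }))
  }
  expect_equal(norm_rows(got), norm_rows(want), tolerance = tol)
}

# exhaustive-permutation Spearman oracle (two-sided), midrank ties
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perms(ry), function(p) stats::cor(rx, p), numeric(1))
  list(rho = rho_obs,
       p = mean(abs(rhos) >= abs(rho_obs) - 1e-9))
}
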