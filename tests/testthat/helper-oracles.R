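# Independent oracles and fixture builders for the test suite.
#
# The polytope oracles work in the null-space coordinates of S and
# enumerate vertices by brute force; they share no code with the package's
# simplex-based solvers.

# small fixture: linear chain  EX_A (uptake) -> R1 -> DM_B (objective)
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_c", "B_c"))
  rxns <- data.frame(id = c("EX_A", "R1", "DM_B"),
                     lb = c(-uptake, 0, 0), ub = c(0, 1000, 1000))
  rxns$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1))
  metabolic_model(mets, rxns, "DM_B", id = "chain")
}

# A -> B via two parallel routes, demand bounded by uptake
parallel_model <- function(uptake = 10, cap1 = 1000, cap2 = 1000) {
  mets <- data.frame(id = c("A_c", "B_c"))
  rxns <- data.frame(id = c("EX_A", "R1", "R2", "DM_B"),
                     lb = c(-uptake, 0, 0, 0), ub = c(0, cap1, cap2, 1000))
  rxns$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1),
                             c(A_c = -1, B_c = 1), c(B_c = -1))
  metabolic_model(mets, rxns, "DM_B", id = "parallel")
}

# two independent linear branches sharing nothing
two_branch_model <- function() {
  mets <- data.frame(id = c("A_c", "B_c", "C_c", "D_c"))
  rxns <- data.frame(id = c("EX_A", "R1", "DM_B", "EX_C", "R2", "DM_D"),
                     lb = c(-10, 0, 0, -7, 0, 0),
                     ub = c(0, 1000, 1000, 0, 1000, 1000))
  rxns$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1),
                             c(C_c = -1), c(C_c = -1, D_c = 1), c(D_c = -1))
  metabolic_model(mets, rxns, "DM_B", id = "branches")
}

# random connected-ish network with modest null-space dimension, always
# feasible at v = 0 (lb <= 0 <= ub)
random_network <- function(seed, n_rxns = 8, n_mets = NULL) {
  stopifnot(n_rxns >= 4)
  set.seed(seed)
  if (is.null(n_mets)) n_mets <- max(2L, n_rxns - sample(2:3, 1))
  repeat {
    S <- matrix(0, n_mets, n_rxns)
    for (j in seq_len(n_rxns)) {
      k <- sample(1:min(3, n_mets), 1)
      rows <- sample(n_mets, k)
      S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (qr(S)$rank < n_mets) next  # keep null-space dimension = n - m
    mets <- data.frame(id = sprintf("m%d_c", seq_len(n_mets)))
    ub <- round(runif(n_rxns, 2, 10), 1)
    lb <- ifelse(runif(n_rxns) < 0.4, -round(runif(n_rxns, 2, 10), 1), 0)
    rxns <- data.frame(id = sprintf("r%d", seq_len(n_rxns)), lb = lb, ub = ub)
    rxns$stoichiometry <- lapply(seq_len(n_rxns), function(j) {
      s <- S[, j]; stats::setNames(s[s != 0], mets$id[s != 0])
    })
    ok <- all(vapply(rxns$stoichiometry, length, integer(1)) > 0)
    if (!ok) next
    return(metabolic_model(mets, rxns, rxns$id[n_rxns],
                           id = sprintf("rand%d", seed)))
  }
}

null_space_basis <- function(S) {
  # orthonormal basis of {v : S v = 0}
  n <- ncol(S)
  qr_t <- qr(t(S))
  r <- qr_t$rank
  if (r == n) return(matrix(0, n, 0))
  qr.Q(qr_t, complete = TRUE)[, (r + 1):n, drop = FALSE]
}

# vertices of {t : G t <= h} (full-dimensional, bounded), brute force over
# row subsets
polytope_vertices <- function(G, h, tol = 1e-7) {
  k <- ncol(G)
  if (k == 0) return(matrix(0, 1, 0))
  verts <- list()
  for (I in utils::combn(nrow(G), k, simplify = FALSE)) {
    GI <- G[I, , drop = FALSE]
    if (abs(det(GI)) < 1e-10) next
    t0 <- tryCatch(solve(GI, h[I]), error = function(e) NULL)
    if (is.null(t0)) next
    if (all(G %*% t0 <= h + tol)) verts[[length(verts) + 1]] <- t0
  }
  if (!length(verts)) return(NULL)
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

# flux-space vertices of {S v = 0, lb <= v <= ub, extra_A v >= extra_b}
flux_vertices <- function(model, extra_A = NULL, extra_b = NULL) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  N <- null_space_basis(S)
  n <- ncol(S)
  G <- rbind(N, -N)
  h <- c(model$rxns$ub, -model$rxns$lb)
  if (!is.null(extra_A)) {
    G <- rbind(G, -matrix(extra_A, ncol = n) %*% N)
    h <- c(h, -extra_b)
  }
  V <- polytope_vertices(G, h)
  if (is.null(V)) return(NULL)
  V %*% t(N)
}

# oracle FBA: maximize flux of objective over enumerated vertices
oracle_fba_max <- function(model, objective_id = model$objective) {
  V <- flux_vertices(model)
  if (is.null(V)) return(NA_real_)
  j <- match(objective_id, model$rxns$id)
  max(V[, j])
}

# oracle GIMME: minimize sum(c |v|) over the polytope intersected with the
# objective constraint, by enumerating sign-orthants of the penalized
# reversible reactions (the objective is linear within each orthant, so
# vertex enumeration is exact there)
oracle_gimme_score <- function(model, cvec, required_fraction = 0.9) {
  n <- nrow(model$rxns)
  cvec <- cvec[model$rxns$id]; cvec[is.na(cvec)] <- 0
  opt <- oracle_fba_max(model)
  extra_A <- NULL; extra_b <- NULL
  if (!is.na(opt) && opt > 1e-6) {
    extra_A <- as.numeric(model$rxns$id == model$objective)
    extra_b <- required_fraction * opt
  }
  pen_rev <- which(cvec > 0 & model$rxns$lb < 0 & model$rxns$ub > 0)
  signs_list <- if (length(pen_rev))
    expand.grid(rep(list(c(1, -1)), length(pen_rev))) else data.frame(dummy = 1)
  best <- Inf
  for (row in seq_len(nrow(signs_list))) {
    A2 <- extra_A; b2 <- extra_b
    if (length(pen_rev)) {
      sg <- as.numeric(signs_list[row, ])
      for (kk in seq_along(pen_rev)) {
        a <- numeric(n); a[pen_rev[kk]] <- sg[kk]
        A2 <- rbind(A2, a); b2 <- c(b2, 0)   # sg * v >= 0
      }
    }
    V <- flux_vertices(model, A2, b2)
    if (is.null(V)) next
    vals <- abs(V) %*% cvec
    best <- min(best, min(vals))
  }
  best
}
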