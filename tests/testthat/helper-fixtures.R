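# Shared fixtures and independent oracles.

# Independent FVA oracle: per-reaction LPs solved by boot::simplex (a
# different solver and formulation from the package's tableau simplex).
# Reactions with lb == ub are substituted out as constants, which
# boot::simplex cannot handle as degenerate rows.
oracle_fva <- function(model) {
  S <- model$S
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # dead-end reduction: a metabolite served by a single non-fixed reaction
  # with no fixed-flux supply forces that reaction to zero; iterate to a
  # fixed point (boot::simplex cannot digest the resulting degenerate rows)
  repeat {
    fixed <- lb == ub
    rhs <- as.numeric(-S[, fixed, drop = FALSE] %*% lb[fixed])
    changed <- FALSE
    for (i in seq_len(nrow(S))) {
      nz <- which(S[i, ] != 0 & !fixed)
      if (length(nz) == 1L && rhs[i] == 0) {
        j <- nz
        stopifnot(lb[j] <= 0, ub[j] >= 0)
        lb[j] <- 0; ub[j] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fixed <- lb == ub
  free <- which(!fixed)
  beq <- as.numeric(-S %*% lb)
  flip <- beq < 0
  A3 <- S[, free, drop = FALSE]
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3 <- abs(beq)
  live <- rowSums(A3 != 0) > 0
  stopifnot(all(b3[!live] == 0))
  A3 <- A3[live, , drop = FALSE]
  b3 <- b3[live]
  nf <- length(free)
  A1 <- diag(nf)
  b1 <- (ub - lb)[free]
  out <- matrix(NA_real_, ncol(S), 2)
  for (j in seq_len(ncol(S))) {
    if (fixed[j]) {
      out[j, ] <- c(lb[j], lb[j])
      next
    }
    a <- numeric(nf)
    a[match(j, free)] <- 1
    lo <- boot::simplex(a, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = FALSE)
    hi <- boot::simplex(a, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = TRUE)
    stopifnot(lo$solved == 1, hi$solved == 1)
    out[j, ] <- c(lo$value + lb[j], hi$value + lb[j])
  }
  data.frame(reaction = model$reactions$id, vmin = out[, 1], vmax = out[, 2])
}

# Gene ids appearing in a model's GPR rules.
model_genes <- function(model) {
  unique(unlist(lapply(model$reactions$gpr, function(g) {
    if (nzchar(g)) amlmetab:::gpr_genes(amlmetab:::parse_gpr(g)) else character(0)
  })))
}

# Small latent-model stand-in holding a given score matrix.
fake_latent <- function(scores) {
  structure(list(scores = scores), class = "latent_model")
}

# Three-class score fixture: n_info informative components carrying one of
# three class-separation patterns, plus pure-noise components.
genomic_score_fixture <- function(n, cls, n_info, n_noise, sep = 2.5) {
  X <- matrix(stats::rnorm(n * (n_info + n_noise)), n)
  for (j in seq_len(n_info)) {
    X[, j] <- X[, j] + sep * scale(as.integer(factor(cls)) * (j %% 3 + 1))
  }
  colnames(X) <- paste0("C", seq_len(ncol(X)))
  rownames(X) <- sprintf("P%04d", seq_len(n))
  X
}

# Tiny two-group metabolite table with planted fold-change shifts.
planted_ms_table <- function(n_per_group = 15, n_shift = 5, n_noise = 25,
                             fold = 10, seed = 1) {
  amlmetab:::with_seed(seed, {
    n <- 2 * n_per_group
    m <- n_shift + n_noise
    X <- matrix(exp(stats::rnorm(n * m, log(1e5), 0.3)), n, m)
    colnames(X) <- c(sprintf("shift_%02d", seq_len(n_shift)),
                     sprintf("noise_%02d", seq_len(n_noise)))
    rownames(X) <- sprintf("S%02d", seq_len(n))
    grp <- rep(c("CD34_AML", "CD34_CB"), each = n_per_group)
    X[grp == "CD34_AML", seq_len(n_shift)] <-
      X[grp == "CD34_AML", seq_len(n_shift)] * fold
    metabolite_table(X, groups = grp)
  })
}
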