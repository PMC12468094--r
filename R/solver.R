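# Quasi-static nonlinear inflation: total-Lagrangian Newton iteration with
# follower pressure on the posterior surface, sliding limbal boundary
# conditions (penalty along the limbal anchoring-cone normal), load stepping
# with step halving, and the backward-displacement fixed point that recovers
# the stress-free reference configuration.

#' Solver configuration
#'
#' @param iop intraocular pressure (mm Hg; 1 mm Hg = 0.133322 kPa)
#' @param load_steps number of equal load steps
#' @param tol relative residual tolerance of the Newton iteration
#' @param max_iter Newton iterations per load step
#' @param max_halvings load-step halvings before giving up
#' @param penalty boundary-condition penalty stiffness (kPa mm)
#' @param bc `"sliding"` (limbal ring free to slide tangentially to the
#'   anchoring cone) or `"pinned"` (ring fully fixed)
#' @return object of class `solve_config`
#' @export
solve_config <- function(iop = 15, load_steps = 5, tol = 1e-8, max_iter = 30,
                         max_halvings = 4, penalty = 1e7,
                         bc = c("sliding", "pinned"),
                         bulk_stages = c(0.01, 0.1, 1)) {
  bc <- match.arg(bc)
  stopifnot(iop >= 0, load_steps >= 1, tol > 0, max_iter >= 1, penalty > 0,
            all(bulk_stages > 0), utils::tail(bulk_stages, 1) == 1)
  structure(list(iop = iop, load_steps = load_steps, tol = tol,
                 max_iter = max_iter, max_halvings = max_halvings,
                 penalty = penalty, bc = bc, bulk_stages = bulk_stages),
            class = "solve_config")
}

scale_bulk <- function(material, f) {
  if (f == 1) return(material)
  material$bulk <- material$bulk * f
  material
}

# Constraints: list(nodes = integer k, dirs = k x 3 unit matrix). Each row
# penalizes displacement along its direction at its node.
default_constraints <- function(mesh, bc = "sliding") {
  if (!length(mesh$limbus_nodes)) return(list(nodes = integer(0), dirs = matrix(0, 0, 3)))
  if (bc == "pinned") {
    k <- length(mesh$limbus_nodes)
    return(list(nodes = rep(mesh$limbus_nodes, each = 3),
                dirs = diag(3)[rep(1:3, k), ]))
  }
  nodes <- mesh$limbus_nodes
  dirs <- mesh$bc_normal
  # remove the in-plane rotation rigid mode: pin the circumferential
  # direction of one deterministic limbal node (max x, then max y)
  xy <- mesh$nodes[nodes, 1:2, drop = FALSE]
  pin <- order(-xy[, 1], -xy[, 2])[1]
  tangent <- c(-xy[pin, 2], xy[pin, 1], 0)
  tangent <- tangent / sqrt(sum(tangent^2))
  list(nodes = c(nodes, nodes[pin]), dirs = rbind(dirs, tangent))
}

constraint_triplets <- function(cons, kpen) {
  k <- length(cons$nodes)
  if (!k) return(list(i = integer(0), j = integer(0), x = numeric(0)))
  ii <- jj <- integer(6 * k); xx <- numeric(6 * k)
  t <- 0L
  for (q in seq_len(k)) {
    d <- cons$dirs[q, ]
    base <- 3L * (cons$nodes[q] - 1L)
    blk <- kpen * outer(d, d)
    for (a in 1:3) for (b in 1:3) {
      if (a < b) next                       # lower triangle only
      t <- t + 1L
      ii[t] <- base + a; jj[t] <- base + b; xx[t] <- blk[a, b]
    }
  }
  list(i = ii, j = jj, x = xx)
}

constraint_force <- function(cons, kpen, u) {
  f <- numeric(length(u))
  for (q in seq_along(cons$nodes)) {
    idx <- 3L * (cons$nodes[q] - 1L) + 1:3
    d <- cons$dirs[q, ]
    f[idx] <- f[idx] + kpen * d * sum(d * u[idx])
  }
  f
}

assemble_system <- function(mesh, material, u, p, want_K, load_stiff = TRUE) {
  fem_assemble(mesh$nodes, mesh$tets - 1L, u,
               material$c_eff, material$k1_eff, material$k2, material$kappa,
               material$bulk, material$A1, material$A2,
               mesh$pressure_faces - 1L, p, want_K, load_stiff)
}

# Newton direction for (M - K_load) du = -R, where M = material/geometric
# stiffness + boundary penalty (SPD, CHOLMOD-factored with cached symbolic
# analysis) and K_load is the exact nonsymmetric follower-load stiffness,
# applied via preconditioned Richardson iteration:
#   du_{k+1} = M^{-1} (-R + K_load du_k).
tangent_solve <- function(cache, asm, pent, R, ndof) {
  xall <- c(asm$Kx, pent$x)
  if (!is.null(cache$K) && !identical(cache$nx, length(xall))) {
    rm(list = ls(cache), envir = cache)   # triplet pattern changed
  }
  cache$nx <- length(xall)
  if (is.null(cache$K)) {
    iall <- c(asm$Ki, pent$i)   # lower-triangle triplets (i >= j)
    jall <- c(asm$Kj, pent$j)
    cache$K <- Matrix::sparseMatrix(i = iall, j = jall, x = xall,
                                    dims = c(ndof, ndof), symmetric = TRUE)
    # map triplets onto the dsCMatrix x-slot (CSC order of the stored
    # triangle; if the upper triangle is stored, entry (i, j) lives at
    # (row j, col i))
    cache$ord <- if (cache$K@uplo == "U") order(iall, jall) else order(jall, iall)
    io <- iall[cache$ord]; jo <- jall[cache$ord]
    newgrp <- c(TRUE, io[-1] != io[-length(io)] | jo[-1] != jo[-length(jo)])
    cache$grp <- cumsum(newgrp)
    stopifnot(cache$grp[length(cache$grp)] == length(cache$K@x))
  }
  Ks <- cache$K
  Ks@x <- as.numeric(rowsum(xall[cache$ord], cache$grp, reorder = FALSE))
  # Factorization: supernodal LL' of P = M + tau D I, with tau = 0 in the
  # regular (positive definite) case. Near follower-pressure limit points M
  # goes indefinite and the attempt fails (CHOLMOD leaks the partial factor
  # of a failed attempt, so the escalated tau is kept for the remainder of
  # this Newton solve); GMRES below corrects for both the shift and the
  # follower-load stiffness, returning the direction of the EXACT tangent.
  # A shift large relative to the softest (limbal sliding) modes would
  # poison their components, hence the gentle ladder.
  dscale <- mean(abs(Matrix::diag(Ks)))
  if (is.null(cache$tau)) cache$tau <- 0
  ch <- NULL
  tau_abs <- 0
  repeat {
    tau_abs <- cache$tau * dscale
    ok <- tryCatch(suppressWarnings({
      Kt <- if (tau_abs > 0) Ks + Matrix::Diagonal(ndof, tau_abs) else Ks
      if (is.null(cache$chol)) {
        cache$chol <- Matrix::Cholesky(Kt, LDL = FALSE, super = TRUE)
      } else {
        cache$chol <- Matrix::update(cache$chol, Kt)
      }
      TRUE
    }), error = function(e) FALSE)
    if (ok) { ch <- cache$chol; break }
    cache$chol <- NULL          # failed update leaves the factor mutated
    # only a shift small relative to the softest (limbal sliding) modes
    # keeps the corrected direction usable; deeper indefiniteness is left
    # to the caller's penalty softening / load stepping (soft-bulk tangents
    # are positive definite in practice)
    if (cache$tau >= 1e-4) return(NULL)
    cache$tau <- 1e-4
  }
  solveM <- function(b) as.numeric(Matrix::solve(ch, b))
  # CHOLMOD factors are external allocations invisible to R's gc heuristics;
  # explicit collection plus malloc_trim keeps long runs flat.
  gc(FALSE)
  mem_trim()
  du <- solveM(-R)
  # left-preconditioned GMRES on the exact system (M - K_load) du = -R with
  # P as preconditioner: P^{-1}(M - KL) v = v - P^{-1}(tau v + KL v)
  KL <- if (length(asm$Lx)) {
    Matrix::sparseMatrix(i = asm$Li, j = asm$Lj, x = asm$Lx,
                         dims = c(ndof, ndof))
  } else NULL
  applyB <- function(v) {
    w <- tau_abs * v
    if (!is.null(KL)) w <- w + as.numeric(KL %*% v)
    v - solveM(w)
  }
  sol <- gmres_solve(applyB, du, maxit = 50, tol = 1e-8)
  if (!is.null(sol) && all(is.finite(sol))) du <- sol
  du
}

# Minimal dense-Hessenberg GMRES (no restarts); returns NULL on stagnation.
gmres_solve <- function(applyA, b, maxit = 40, tol = 1e-8) {
  n <- length(b)
  beta <- sqrt(sum(b^2))
  if (beta == 0) return(b)
  V <- matrix(0, n, maxit + 1)
  H <- matrix(0, maxit + 1, maxit)
  V[, 1] <- b / beta
  g <- c(beta, numeric(maxit))
  cs <- sn <- numeric(maxit)
  for (j in seq_len(maxit)) {
    w <- applyA(V[, j])
    for (i in seq_len(j)) {
      H[i, j] <- sum(w * V[, i])
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1, j] <- sqrt(sum(w^2))
    if (H[j + 1, j] > 1e-14 * beta) V[, j + 1] <- w / H[j + 1, j]
    # apply accumulated Givens rotations
    for (i in seq_len(j - 1)) {
      t1 <- cs[i] * H[i, j] + sn[i] * H[i + 1, j]
      H[i + 1, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1, j]
      H[i, j] <- t1
    }
    d <- sqrt(H[j, j]^2 + H[j + 1, j]^2)
    if (d == 0) return(NULL)
    cs[j] <- H[j, j] / d; sn[j] <- H[j + 1, j] / d
    H[j, j] <- d; H[j + 1, j] <- 0
    g[j + 1] <- -sn[j] * g[j]
    g[j] <- cs[j] * g[j]
    if (abs(g[j + 1]) <= tol * beta || j == maxit) {
      y <- backsolve(H[seq_len(j), seq_len(j), drop = FALSE], g[seq_len(j)])
      return(as.numeric(V[, seq_len(j), drop = FALSE] %*% y))
    }
  }
  NULL
}

# One Newton solve at fixed pressure, with a backtracking line search on the
# residual norm (the exponential fiber law punishes overshoot) and element
# inversion treated as an automatic backtrack.
newton_solve <- function(mesh, material, p, u, cons, cfg, pent,
                         cache = new.env(parent = emptyenv())) {
  ndof <- 3L * nrow(mesh$nodes)
  residual_at <- function(uu) {
    asm <- assemble_system(mesh, material, uu, p, FALSE)
    if (!isTRUE(asm$ok)) return(NULL)
    R <- asm$fint - asm$fext + constraint_force(cons, cfg$penalty, uu)
    nrm <- sqrt(sum(R^2))
    if (!is.finite(nrm)) return(NULL)   # e.g. fiber exponential overflow
    list(R = R, norm = nrm, fref = sqrt(sum(asm$fext^2)))
  }
  hist_norm <- rep(Inf, 5)   # non-monotone (Grippo) reference window
  best_norm <- Inf
  for (it in seq_len(cfg$max_iter)) {
    asm <- assemble_system(mesh, material, u, p, TRUE)
    if (!isTRUE(asm$ok)) {
      return(list(ok = FALSE, u = u, reason = "element inversion"))
    }
    R <- asm$fint - asm$fext + constraint_force(cons, cfg$penalty, u)
    fref <- sqrt(sum(asm$fext^2))
    normR <- sqrt(sum(R^2))
    conv <- max(cfg$tol * fref, 1e-12)
    if (normR <= conv) {
      return(list(ok = TRUE, u = u, iters = it, normR = normR))
    }
    best_norm <- min(best_norm, normR)
    if (normR > 50 * best_norm) {
      return(list(ok = FALSE, u = u, reason = "divergence"))
    }
    hist_norm[(it - 1L) %% 5L + 1L] <- normR
    ref_norm <- max(hist_norm[is.finite(hist_norm)])
    step <- tangent_solve(cache, asm, pent, R, ndof)
    if (is.null(step) || !all(is.finite(step))) {
      return(list(ok = FALSE, u = u, reason = "singular tangent"))
    }
    # trust-region cap: near-singular tangents produce huge steps that the
    # exponential fiber law punishes; cap keeps the line search effective
    smax <- max(abs(step))
    if (smax > 0.2) step <- step * (0.2 / smax)
    # non-monotone backtracking: accept decrease w.r.t. the recent maximum,
    # which rides through limit-point humps where a monotone search stalls
    # into expensive load-halving cascades
    s <- 1
    accepted <- FALSE
    for (ls in 0:10) {
      trial <- residual_at(u + s * step)
      if (!is.null(trial) &&
          (trial$norm < ref_norm * (1 - 1e-4 * s) || trial$norm <= conv)) {
        u <- u + s * step
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) {
      return(list(ok = FALSE, u = u, reason = "line search stalled"))
    }
  }
  # final convergence check after the iteration budget
  fin <- residual_at(u)
  if (!is.null(fin) && fin$norm <= max(cfg$tol * fin$fref, 1e-12)) {
    return(list(ok = TRUE, u = u, iters = cfg$max_iter, normR = fin$norm))
  }
  list(ok = FALSE, u = u, reason = "iteration budget")
}

#' Inflate a corneal mesh to intraocular pressure
#'
#' Solves quasi-static equilibrium under follower pressure on the posterior
#' surface. Limbal ring nodes are constrained against displacement along the
#' anchoring-cone normal (free to slide tangentially); rigid-body modes are
#' removed. Load is applied in equal steps with step halving on divergence.
#'
#' @param mesh a `corneal_mesh` (its `nodes` are the reference configuration)
#' @param material a [material_field()]
#' @param config a [solve_config()]
#' @param u0 optional displacement warm start (tried at full load first)
#' @param constraints optional constraint list overriding the mesh defaults
#' @param cache optional solver cache (sparsity pattern, factorization,
#'   regularization state) shared across repeated inflations of the same
#'   mesh, e.g. by [find_stress_free()]
#' @return object of class `solve_result`: displacement `u` (3n), `deformed`
#'   coordinates, `apical_rise` (mm, anterior-positive), convergence
#'   `history`, `max_volume_change`
#' @export
inflate <- function(mesh, material, config = solve_config(), u0 = NULL,
                    constraints = NULL, cache = NULL) {
  cons <- constraints %||% default_constraints(mesh, config$bc)
  pent <- constraint_triplets(cons, config$penalty)
  p_full <- config$iop * MMHG_TO_KPA
  ndof <- 3L * nrow(mesh$nodes)
  history <- list()
  solved <- FALSE
  cache <- cache %||% new.env(parent = emptyenv())
  # let the indefiniteness handling relax every second inflation so that
  # transient limit-point phases do not slow later solves permanently
  if ((cache$tau %||% 0) > 0) {
    cache$tau <- 0
    cache$chol <- NULL
  }
  if (!is.null(u0) && p_full > 0) {
    # warm start: single solve at full load and full penalty
    r <- newton_solve(mesh, material, p_full, u0, cons, config, pent, cache)
    if (r$ok) {
      u <- r$u; history <- list(c(p = p_full, bulk = 1, iters = r$iters))
      solved <- TRUE
    } else {
      # second chance: re-soften the volumetric penalty but keep the guess;
      # drop any indefiniteness shift (soft-bulk tangents are definite)
      cache$tau <- 0; cache$chol <- NULL
      u_try <- u0
      ok2 <- TRUE
      for (f in config$bulk_stages) {
        r2 <- newton_solve(mesh, scale_bulk(material, f), p_full, u_try, cons,
                           config, pent, cache)
        if (!r2$ok) { ok2 <- FALSE; break }
        u_try <- r2$u
        history[[length(history) + 1L]] <- c(p = p_full, bulk = f, iters = r2$iters)
      }
      if (ok2) { u <- u_try; solved <- TRUE } else {
        history <- list()
        cache$tau <- 0; cache$chol <- NULL
      }
    }
  }
  if (!solved) {
    # Cold start. The displacement-based volumetric penalty makes full-
    # stiffness Newton steps explode (second-order volume errors are
    # amplified by the bulk modulus), so the load ramp runs at a softened
    # penalty and the full penalty is restored by continuation at full load.
    stages <- config$bulk_stages
    u <- numeric(ndof)
    pc <- 0
    targets <- p_full * seq_len(config$load_steps) / config$load_steps
    if (p_full == 0) targets <- 0
    nh <- 0L
    mat_soft <- scale_bulk(material, stages[1])
    while (length(targets)) {
      pt <- targets[1]
      r <- newton_solve(mesh, mat_soft, pt, u, cons, config, pent, cache)
      if (r$ok) {
        u <- r$u; pc <- pt
        history[[length(history) + 1L]] <- c(p = pt, bulk = stages[1], iters = r$iters)
        targets <- targets[-1]
      } else {
        nh <- nh + 1L
        if (nh > config$max_halvings * config$load_steps) {
          stop_cxl(sprintf("inflation failed to converge (%s at p = %.4g kPa after %d halvings)",
                           r$reason, pt, nh), "cxl_solver_error")
        }
        targets <- c((pc + pt) / 2, targets)
      }
    }
    # penalty continuation at full load
    stq <- stages[-1]
    nh <- 0L
    fprev <- stages[1]
    while (length(stq)) {
      f <- stq[1]
      r <- newton_solve(mesh, scale_bulk(material, f), p_full, u, cons,
                        config, pent, cache)
      if (r$ok) {
        u <- r$u
        history[[length(history) + 1L]] <- c(p = p_full, bulk = f, iters = r$iters)
        fprev <- f
        stq <- stq[-1]
      } else {
        nh <- nh + 1L
        if (nh > 8L) {
          stop_cxl(sprintf("penalty continuation failed (%s at stage %.3g)",
                           r$reason, f), "cxl_solver_error")
        }
        stq <- c(sqrt(fprev * f), stq)
      }
    }
  }
  vols <- fem_volumes(mesh$nodes, mesh$tets - 1L, u)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  apex <- if (length(mesh$anterior_nodes) && !is.null(mesh$grid)) {
    mesh$anterior_nodes[which.min(mesh$rlat[mesh$anterior_nodes])]
  } else NA_integer_
  structure(list(
    u = u, deformed = mesh$nodes + U,
    apex_node = apex,
    apical_rise = if (is.na(apex)) NA_real_ else -U[apex, 3],
    history = history,
    max_volume_change = max(abs(vols$vol / vols$vol0 - 1)),
    iop = config$iop, converged = TRUE), class = "solve_result")
}

#' Recover the stress-free reference configuration
#'
#' Backward-displacement fixed point: `X <- X_target - U(X)` (optionally
#' under-relaxed), iterated until the re-inflated anterior surface matches
#' the target geometry within `tol`. The material field is re-evaluated on
#' each updated reference.
#'
#' @param mesh a `corneal_mesh` whose nodes are the target (measured)
#'   geometry
#' @param material_fn function taking a mesh and returning a
#'   [material_field()] (re-evaluated every iteration)
#' @param config a [solve_config()]
#' @param tol anterior-surface round-trip residual tolerance (mm; 1e-3 = 1 um)
#' @param max_iter fixed-point iteration budget
#' @param relax initial relaxation factor in (0, 1]; subsequent factors are
#'   set adaptively (Aitken delta-squared acceleration)
#' @param X_init optional initial guess for the stress-free coordinates
#'   (e.g. the result for a nearby IOP), used to warm-start the fixed point
#' @return object of class `prestress_result`: `mesh0` (stress-free mesh),
#'   `solution` (inflation from `mesh0`), `residual` (mm), `iterations`,
#'   `trace`
#' @export
find_stress_free <- function(mesh, material_fn, config = solve_config(),
                             tol = 1e-3, max_iter = 20, relax = 1,
                             X_init = NULL) {
  X_target <- mesh$nodes
  m <- mesh
  if (!is.null(X_init)) m$nodes <- X_init
  u_ws <- NULL
  trace <- numeric(0)
  r_prev <- NULL
  omega <- relax
  X_good <- NULL; r_good <- NULL; u_good <- NULL
  nfail <- 0L
  it <- 0L
  solver_cache <- new.env(parent = emptyenv())
  while (it < max_iter) {
    sol <- tryCatch(inflate(m, material_fn(m), config, u0 = u_ws,
                            cache = solver_cache),
                    cxl_solver_error = function(e) NULL)
    if (is.null(sol)) {
      # extrapolation pushed the reference into an unsolvable state:
      # back off towards the last good reference
      nfail <- nfail + 1L
      if (is.null(X_good) || nfail > 5L) {
        stop_cxl("pre-stress inflation failed and no recoverable state remains",
                 "cxl_solver_error")
      }
      omega <- omega / 2
      m$nodes <- X_good + omega * r_good
      u_ws <- u_good
      r_prev <- NULL
      next
    }
    it <- it + 1L
    xd <- sol$deformed
    r <- X_target - xd
    resid <- max(sqrt(rowSums(r^2))[m$anterior_nodes])
    trace <- c(trace, resid)
    if (resid <= tol) {
      return(structure(list(mesh0 = m, solution = sol, residual = resid,
                            iterations = it, trace = trace, converged = TRUE),
                       class = "prestress_result"))
    }
    if (!is.null(r_prev)) {
      dr <- r - r_prev
      den <- sum(dr * dr)
      if (den > 0) omega <- -omega * sum(r_prev * dr) / den
      omega <- min(max(omega, 0.25), 3)
    }
    r_prev <- r
    X_good <- m$nodes; r_good <- r; u_good <- sol$u
    m$nodes <- m$nodes + omega * r
    u_ws <- sol$u
  }
  stop_cxl(sprintf("pre-stress fixed point did not converge in %d iterations (residual %.3g mm; trace: %s)",
                   max_iter, trace[length(trace)],
                   paste(signif(trace, 3), collapse = ", ")),
           "cxl_solver_error")
}

# Algebraic least-squares sphere radius of a point cloud.
fit_sphere_radius <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  beta <- qr.solve(A, b)
  sqrt(beta[4] + sum(beta[1:3]^2))
}

#' Apical-rise tangential modulus at an intraocular pressure
#'
#' Estimator (documented, fixed): two inflations of the same reference at
#' `iop - dp` and `iop + dp`; per pressure, the membrane stress is
#' `sigma = p R / (2 t)` with `R` the best-fit sphere radius of the deformed
#' anterior surface (central 6 mm) and `t` the deformed apical thickness;
#' the strain is the apical rise divided by the reference anterior radius.
#' The modulus is the central-difference slope `d sigma / d eps` (kPa).
#'
#' @param mesh a `corneal_mesh` (used directly as the reference, matching an
#'   ex vivo inflation-curve protocol)
#' @param material a [material_field()]
#' @param iop probe pressure (mm Hg)
#' @param dp half-window (mm Hg)
#' @param config a [solve_config()] template
#' @return tangential modulus (kPa)
#' @export
tangential_modulus_at_iop <- function(mesh, material, iop = 15, dp = 0.5,
                                      config = solve_config()) {
  stopifnot(!is.null(mesh$grid))
  ant <- mesh$anterior_nodes
  central <- ant[mesh$rlat[ant] <= 3]
  R_ref <- fit_sphere_radius(mesh$nodes[central, , drop = FALSE])
  apex_a <- ant[which.min(mesh$rlat[ant])]
  post <- mesh$posterior_nodes
  apex_p <- post[which.min(mesh$rlat[post])]
  probe <- function(iop_i, u0 = NULL) {
    cfg <- config; cfg$iop <- iop_i
    sol <- inflate(mesh, material, cfg, u0 = u0)
    Rdef <- fit_sphere_radius(sol$deformed[central, , drop = FALSE])
    tdef <- sqrt(sum((sol$deformed[apex_a, ] - sol$deformed[apex_p, ])^2))
    list(sigma = (iop_i * MMHG_TO_KPA) * Rdef / (2 * tdef),
         eps = sol$apical_rise / R_ref, u = sol$u)
  }
  lo <- probe(iop - dp)
  hi <- probe(iop + dp, u0 = lo$u)
  (hi$sigma - lo$sigma) / (hi$eps - lo$eps)
}
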