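#' Construct the eight-node regulatory-network model
#'
#' Node 1 is a Hill self-activation core
#' dx1/dt = B(p) + A(p) * x1^2/(1 + x1^2) - d*x1 whose operating point
#' x_s is the tangency point where the Hill slope equals the degradation
#' rate d (solved by uniroot at construction).  The control parameter
#' deforms the kinetics in two regimes joined continuously at p = 0:
#' for p < 0 the Hill amplitude and basal rate co-vary
#' (A = 1 + c*p/d, B = d*x_s - A*h(x_s)) so that x_s stays a fixed point
#' whose eigenvalue is exactly c*p — the state does not drift while its
#' restoring force decays linearly, the pure "critical slowing down"
#' scenario; at p = 0 the fixed point and the saddle coincide (fold
#' tangency, eigenvalue 0); for p >= 0 the basal rate is pushed past the
#' fold (A = 1, B = b_c + foldOffset + basalScale*p) so no low fixed
#' point remains and the system escapes through the saddle-node ghost to
#' the distant high state, the small foldOffset placing the escape time
#' inside a sampling window rather than at infinity.  Nodes 2-8 form a mixed activation/repression Hill cascade
#' driven by node 1 (unit degradation each), so the dominant Jacobian
#' eigenvalue is node 1's and crosses zero at p = 0 while critical
#' fluctuations propagate through the cascade.  States live at
#' `stateScale` times the dimensionless units, which sets how large a
#' given absolute noise strength is relative to the dynamics.
#'
#' @param sigma default additive noise strength (default 0.01).
#' @return a [GrnModel-class].
#' @export
grnModel <- function(sigma = 0.01) {
    d <- 0.5; K <- 1; h <- 2
    # tangency: hill'(x) = 2x/(1+x^2)^2 = d, lower root (below K/sqrt(3))
    xS <- stats::uniroot(function(x) 2 * x / (1 + x^2)^2 - d,
                         c(1e-6, 1 / sqrt(3)), tol = 1e-12)$root
    bc <- d * xS - xS^2 / (1 + xS^2)
    edges <- data.frame(
        from = c("n1", "n1", "n2", "n3", "n4", "n5", "n2"),
        to   = c("n2", "n3", "n4", "n5", "n6", "n7", "n8"),
        sign = c(+1, -1, +1, +1, -1, +1, -1))
    new("GrnModel", nodes = paste0("n", 1:8), edges = edges,
        params = list(d = d, K = K, h = h, basalScale = 0.02,
                      eigenSlope = 2,
                      basalCritical = bc, xSaddle = xS,
                      couplingK = c(layer1 = 0.25, layer2 = 0.5),
                      basalDownstream = 0.1, ampDownstream = 2,
                      stateScale = 10,
                      foldOffset = 0.02),
        sigma = sigma)
}

# node-1 kinetic coefficients at parameter p (dimensionless units):
# p < 0 pins the fixed point at xSaddle with eigenvalue eigenSlope * p;
# p >= 0 pushes the basal rate past the fold
.grnNode1Coefs <- function(p, prm) {
    h0 <- prm$xSaddle^2 / (1 + prm$xSaddle^2)
    if (p < 0) {
        A <- 1 + prm$eigenSlope * p / prm$d
        list(A = A, B = prm$d * prm$xSaddle - A * h0)
    } else {
        list(A = 1, B = prm$basalCritical + prm$foldOffset +
                        prm$basalScale * p)
    }
}

# drift field of the model at state x (length 8) and parameter p
.grnDrift <- function(x, p, prm) {
    hp <- function(u, K) u^2 / (K^2 + u^2)     # activating Hill, h = 2
    hm <- function(u, K) K^2 / (K^2 + u^2)     # repressing Hill
    k1 <- prm$couplingK[["layer1"]]; k2 <- prm$couplingK[["layer2"]]
    b <- prm$basalDownstream
    sc <- prm$stateScale
    n1 <- .grnNode1Coefs(p, prm)
    a <- prm$ampDownstream
    x <- x / sc
    sc * c(n1$B + n1$A * hp(x[1L], prm$K) - prm$d * x[1L],
      b + a * hp(x[1L], k1) - x[2L],
      b + a * hm(x[1L], k1) - x[3L],
      b + a * hp(x[2L], k2) - x[4L],
      b + a * hp(x[3L], k2) - x[5L],
      b + a * hm(x[4L], k2) - x[6L],
      b + a * hp(x[5L], k2) - x[7L],
      b + a * hm(x[2L], k2) - x[8L])
}

#' Jacobian eigenvalues of the model at its node-1 fixed point
#'
#' Finds the smallest non-negative fixed point of node 1 at parameter `p`
#' (the low branch where it exists) and returns the real parts of the
#' Jacobian eigenvalues there.  Used to verify numerically that the
#' dominant eigenvalue crosses zero at p = 0.
#'
#' @param model a [GrnModel-class].
#' @param p control-parameter value.
#' @return numeric(8) of eigenvalue real parts, sorted decreasing, or NULL
#'   when no low-branch fixed point exists (p past the bifurcation).
#' @export
grnDominantEigen <- function(model, p) {
    prm <- model@params
    n1 <- .grnNode1Coefs(p, prm)
    f1 <- function(x) n1$B + n1$A * x^2 / (1 + x^2) - prm$d * x
    x1 <- if (p < 0) prm$xSaddle else {
        lo <- 1e-8; hi <- prm$xSaddle
        if (f1(lo) * f1(hi) > 0) return(NULL)
        stats::uniroot(f1, c(lo, hi), tol = 1e-12)$root
    }
    x0 <- prm$stateScale * c(x1, rep(0.5, 7))
    for (i in 1:400) x0 <- x0 + 0.2 * .grnDrift(x0, p, prm)  # relax cascade
    J <- numeric(0)
    eps <- 1e-6
    J <- vapply(1:8, function(j) {
        e <- numeric(8); e[j] <- eps
        (.grnDrift(x0 + e, p, prm) - .grnDrift(x0 - e, p, prm)) / (2 * eps)
    }, numeric(8))
    sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
}

#' Simulate the regulatory network at one parameter value
#'
#' Euler-Maruyama integration with additive white noise of strength
#' `sigma`; states are floored at 1e-6 to stay strictly positive for
#' downstream log handling.  After `burnIn` steps, `nSamples` states are
#' recorded every `sampleEvery` steps.
#'
#' @param model a [GrnModel-class].
#' @param p control-parameter value.
#' @param nSamples states to record (default 50).
#' @param burnIn integration steps before recording (default 2000; 100
#'   time units, enough for relaxation and for the post-bifurcation
#'   escape through the saddle-node ghost).
#' @param dt step size (default 0.05).
#' @param sampleEvery steps between recorded states (default 20, i.e.
#'   one time unit apart, so consecutive samples decorrelate except very
#'   close to the bifurcation).
#' @param sigma noise strength; defaults to the model's.
#' @param seed RNG seed.
#' @param init initial state (length 8); default rep(0.2, 8), near the
#'   low branch.  Pass the previous parameter's final state for a
#'   quasi-static sweep.
#' @return 8 x nSamples matrix of sampled states, with the final state in
#'   `attr(, "finalState")`.
#' @export
simulateGrn <- function(model, p, nSamples = 50L, burnIn = 2000L, dt = 0.05,
                        sampleEvery = 20L, sigma = model@sigma, seed = NULL,
                        init = NULL) {
    stopifnot(sigma >= 0, dt > 0, nSamples >= 1L)
    prm <- model@params
    x <- if (is.null(init)) rep(0.2 * model@params$stateScale, 8)
         else as.numeric(init)
    out <- matrix(NA_real_, 8L, nSamples,
                  dimnames = list(model@nodes, paste0("s", seq_len(nSamples))))
    sq <- sigma * sqrt(dt)
    .withSeed(seed, {
        nTot <- burnIn + nSamples * sampleEvery
        noise <- if (sigma > 0) matrix(stats::rnorm(8L * nTot, sd = sq), 8L)
                 else NULL
        k <- 0L
        for (step in seq_len(nTot)) {
            x <- x + .grnDrift(x, p, prm) * dt
            if (!is.null(noise)) x <- x + noise[, step]
            x[x < 1e-6] <- 1e-6
            if (any(!is.finite(x)))
                stop(sprintf("divergent trajectory at p = %g, dt = %g", p, dt))
            if (step > burnIn && (step - burnIn) %% sampleEvery == 0L) {
                k <- k + 1L
                out[, k] <- x
            }
        }
    })
    attr(out, "finalState") <- x
    out
}

#' Sweep the control parameter and score each grid point with mNFE
#'
#' Simulates the model over `pGrid` quasi-statically (each grid point
#' starts from the previous one's final state), takes the first two grid
#' points' samples as the reference set, infers the reference association
#' network, and scores every sample of every later grid point as a single
#' case sample with the mNFE pipeline; per-grid-point scores are averaged.
#' The sudden rise of the curve as the grid approaches the bifurcation at
#' p = 0 is the early-warning signal the simulator is designed to probe.
#'
#' @param model a [GrnModel-class].
#' @param pGrid ascending parameter grid containing 0; at least 3 points
#'   (default seq(-0.5, 0.25, by = 0.05)).
#' @param nSamples samples per grid point (default 50).
#' @param sigma noise strength (default the model's).
#' @param seed RNG seed (drives simulation and StARS subsampling).
#' @param burnIn,dt,sampleEvery passed to [simulateGrn()].
#' @param nLambda,lambdaMinRatio network-inference settings.
#' @param stability penalty selection for the reference network: the
#'   default `"fixed"` (mid-path penalty) suits this small, strongly
#'   coupled 8-node system, where StARS — designed for sparse
#'   high-dimensional graphs — finds no stable sparse regime;
#'   `"stars"` re-enables stability selection.
#' @return list with `curve` (data.frame p, score), `argmax` (p value with
#'   the largest score), `arn`, and the per-point sample list.
#' @export
sweepAndScore <- function(model, pGrid = seq(-0.5, 0.25, by = 0.05),
                          nSamples = 50L, sigma = model@sigma, seed = NULL,
                          burnIn = 0L, dt = 0.05, sampleEvery = 80L,
                          nLambda = 20L, lambdaMinRatio = 0.01,
                          stability = "fixed") {
    if (length(pGrid) < 3L) stop("parameter grid must have at least 3 points")
    if (any(diff(pGrid) <= 0)) stop("parameter grid must be ascending")
    sims <- vector("list", length(pGrid))
    init <- NULL
    seeds <- .spawnSeeds(seed, length(pGrid) + 1L)
    for (i in seq_along(pGrid)) {
        sims[[i]] <- simulateGrn(model, pGrid[i], nSamples = nSamples,
            burnIn = if (i == 1L) burnIn + 1000L else burnIn,
            dt = dt, sampleEvery = sampleEvery,
            sigma = sigma, seed = seeds[[i]], init = init)
        colnames(sims[[i]]) <- sprintf("p%02d_s%02d", i, seq_len(nSamples))
        init <- attr(sims[[i]], "finalState")
    }
    reference <- cbind(sims[[1L]], sims[[2L]])
    # continuous, strictly positive data: no pseudocount, no prevalence filter
    arn <- inferMbNetwork(reference, lambdaMinRatio = lambdaMinRatio,
        nLambda = nLambda, prevalenceMin = 0, pseudocount = 0,
        stability = stability, seed = seeds[[length(seeds)]])
    nfeRef <- networkNfe(arn, .closeColumns(
        reference[, order(colnames(reference)), drop = FALSE], 0)[arn@nodes, ,
        drop = FALSE])
    refOrdered <- reference[, order(colnames(reference)), drop = FALSE]
    score <- rep(NA_real_, length(pGrid))
    for (i in seq(3L, length(pGrid))) {
        s <- vapply(seq_len(nSamples), function(j) {
            cs <- sims[[i]][, j]
            ssan <- buildSsan(refOrdered, cs, arn, day = pGrid[i])
            mnfe(mnfeScore(arn, ssan, refOrdered, cs, day = pGrid[i],
                           pseudocount = 0, nfeReference = nfeRef))
        }, numeric(1))
        score[i] <- mean(s)
    }
    scored <- !is.na(score)
    list(curve = data.frame(p = pGrid, score = score),
         argmax = pGrid[scored][which.max(score[scored])],
         arn = arn, samples = sims)
}

# derive child seeds (< 2^31) from one base seed
.spawnSeeds <- function(seed, n) {
    if (is.null(seed)) return(rep(list(NULL), n))
    .withSeed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

#' Generate a synthetic longitudinal microbiome cohort
#'
#' Latent per-sample log-abundances are drawn from a multivariate normal
#' whose covariance follows a sparse chain association network; counts are
#' multinomial at the given sequencing depth.  Symptomatic individuals
#' carry a DNB block whose behavior over the `rampLength` time points
#' before the programmed transition reproduces the three DNB conditions:
#' intra-block correlation rises towards `dnbRhoMax`, per-taxon standard
#' deviation rises by `dnbSdMultiplier`, and block-to-outside correlation
#' falls towards zero (the block decouples from the baseline field).  At
#' and after the transition the block's mean shifts by `diseaseShift` (the
#' new disease state) with baseline covariance.
#'
#' @param nControl,nSeroconverter,nT1dCase individuals per group
#'   (defaults 10, 3, 2: five symptomatic in total).
#' @param nTaxa number of taxa (default 40).
#' @param nTimePoints time points per individual (default 12), at days
#'   30, 60, ...
#' @param transitionIndex time-point index of the programmed transition
#'   for symptomatic individuals (default 9).
#' @param dnbSize DNB block size (default 8).
#' @param dnbSdMultiplier peak block standard-deviation multiplier
#'   (default 5).
#' @param dnbRhoMax peak intra-block correlation (default 0.95).
#' @param rampLength time points over which the block ramps up before the
#'   transition (default 3).
#' @param diseaseShift post-transition mean shift of the block on the
#'   latent log scale (default 2.5).
#' @param baseSd baseline latent log-abundance standard deviation
#'   (default 0.5).
#' @param chainPartial partial correlation of the latent chain network
#'   (default 0.45).
#' @param depth multinomial sequencing depth per sample (default 20000).
#' @param seed RNG seed.
#' @return list with `profile` (a [TaxonProfile-class] of counts), `truth`
#'   (data.frame individual, group, transitionDay), `dnbTaxa`, `latent`
#'   (the latent log-abundance matrix) and the generator settings.
#' @export
generateCohort <- function(nControl = 10L, nSeroconverter = 3L, nT1dCase = 2L,
                           nTaxa = 40L, nTimePoints = 12L,
                           transitionIndex = 9L, dnbSize = 8L,
                           dnbSdMultiplier = 5, dnbRhoMax = 0.95,
                           rampLength = 3L, diseaseShift = 2.5,
                           baseSd = 0.5, chainPartial = 0.45,
                           depth = 20000L, seed = NULL) {
    if (dnbSize > nTaxa) stop("DNB block larger than taxa count")
    if (transitionIndex <= rampLength + 1L || transitionIndex > nTimePoints)
        stop("transitionIndex must leave room for the ramp and lie in range")
    taxa <- sprintf("taxon%03d", seq_len(nTaxa))
    dnb <- taxa[seq_len(dnbSize)]
    days <- 30 * seq_len(nTimePoints)
    # chain-graph covariance: precision with off-diagonal band
    Omega <- diag(nTaxa)
    for (i in seq_len(nTaxa - 1L)) Omega[i, i + 1L] <- Omega[i + 1L, i] <- -chainPartial
    Sigma <- solve(Omega)
    Sigma <- Sigma / mean(diag(Sigma)) * baseSd^2
    cholS <- chol(Sigma)
    inds <- c(sprintf("ctrl%02d", seq_len(nControl)),
              sprintf("sero%02d", seq_len(nSeroconverter)),
              sprintf("case%02d", seq_len(nT1dCase)))
    groups <- rep(c("control", "seroconverter", "T1D-case"),
                  c(nControl, nSeroconverter, nT1dCase))
    .withSeed(seed, {
        mu <- stats::rnorm(nTaxa, 0, 1.2)
        allCounts <- NULL; meta <- NULL; latentAll <- NULL
        for (ii in seq_along(inds)) {
            sym <- groups[ii] != "control"
            for (t in seq_len(nTimePoints)) {
                y <- mu + as.vector(stats::rnorm(nTaxa) %*% cholS)
                if (sym) {
                    w <- if (t >= transitionIndex - rampLength && t < transitionIndex)
                             (t - (transitionIndex - rampLength - 1L)) / rampLength
                         else 0
                    if (w > 0) {
                        s <- baseSd * (1 + (dnbSdMultiplier - 1) * w)
                        rho <- dnbRhoMax * w
                        shared <- stats::rnorm(1L)
                        spike <- mu[seq_len(dnbSize)] +
                            s * (sqrt(rho) * shared +
                                 sqrt(1 - rho) * stats::rnorm(dnbSize))
                        y[seq_len(dnbSize)] <- (1 - w) * y[seq_len(dnbSize)] +
                            w * spike
                    }
                    if (t >= transitionIndex)
                        y[seq_len(dnbSize)] <- y[seq_len(dnbSize)] + diseaseShift
                }
                pr <- exp(y - max(y)); pr <- pr / sum(pr)
                cnt <- as.vector(stats::rmultinom(1L, depth, pr))
                allCounts <- cbind(allCounts, cnt)
                latentAll <- cbind(latentAll, y)
                meta <- rbind(meta, data.frame(
                    sample_id = sprintf("%s_d%04d", inds[ii], days[t]),
                    individual = inds[ii], day = days[t], group = groups[ii]))
            }
        }
    })
    rownames(allCounts) <- taxa
    colnames(allCounts) <- meta$sample_id
    rownames(latentAll) <- taxa
    colnames(latentAll) <- meta$sample_id
    profile <- TaxonProfile(allCounts, individual = meta$individual,
                            day = meta$day, group = meta$group)
    truth <- data.frame(individual = inds, group = groups,
        transitionDay = ifelse(groups == "control", NA_real_,
                               days[transitionIndex]))
    list(profile = profile, truth = truth, dnbTaxa = dnb,
         latent = latentAll,
         settings = list(nControl = nControl,
             nSeroconverter = nSeroconverter, nT1dCase = nT1dCase,
             nTaxa = nTaxa, nTimePoints = nTimePoints,
             transitionIndex = transitionIndex, transitionDay = days[transitionIndex],
             dnbSize = dnbSize, dnbSdMultiplier = dnbSdMultiplier,
             dnbRhoMax = dnbRhoMax, rampLength = rampLength,
             diseaseShift = diseaseShift, baseSd = baseSd,
             chainPartial = chainPartial, depth = depth, seed = seed))
}
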