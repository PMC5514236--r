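# Batched block-diagonal elementary FIMs over a dose grid.
#
# The grid scan in optimize_next_dose() needs the elementary FIM of the
# candidate group at every dose on the grid. Concentration is linear in
# dose, so every finite-difference response evaluation can be done for
# all doses at once (a doses x times matrix built from the unit-dose
# profile), leaving only cheap per-dose linear algebra. The derivative
# scheme (central differences, relative step 1e-5 with the same floors)
# is identical to elementary_fim(); a test pins the agreement.

# typical response for all doses at once: doses x times matrix
.resp_all_doses <- function(doses, times, fx) {
  cu <- pk_concentration(times, 1, cl = fx[["cl"]], v = fx[["v"]],
                         ka = fx[["ka"]])
  conc <- outer(doses, cu)
  effect_mean(conc, base = fx[["base"]], emax = fx[["emax"]],
              ec50 = fx[["ec50"]], gamma = fx[["gamma"]])
}

# list of per-dose block-diagonal elementary FIMs (estimated params only)
.batch_block_fims <- function(theta, doses, times) {
  eb <- estimated_beta(theta)
  el <- estimated_lambda(theta)
  fx <- unclass(theta$fixed)
  om <- theta$random$omega2[.eta_names]
  sa <- theta$random$sigma2_add
  sp <- theta$random$sigma2_prop
  nd <- length(doses); nt <- length(times)

  f0 <- .resp_all_doses(doses, times, fx)

  # dE/deta at eta = 0 (absolute step 1e-5, as in fo_moments)
  L <- vector("list", 4)
  names(L) <- .eta_names
  for (k in .eta_names) {
    h <- 1e-5
    fp <- fx; fp[[k]] <- fx[[k]] * exp(h)
    fm <- fx; fm[[k]] <- fx[[k]] * exp(-h)
    L[[k]] <- (.resp_all_doses(doses, times, fp) -
                 .resp_all_doses(doses, times, fm)) / (2 * h)
  }

  # dE/dbeta for estimated fixed effects (relative 1e-5, floor 1e-8)
  M <- vector("list", length(eb))
  names(M) <- eb
  for (p in eb) {
    h <- fd_step(fx[[p]])
    fp <- fx; fp[[p]] <- fx[[p]] + h
    fm <- fx; fm[[p]] <- fx[[p]] - h
    M[[p]] <- (.resp_all_doses(doses, times, fp) -
                 .resp_all_doses(doses, times, fm)) / (2 * h)
  }

  nb <- length(eb); nl <- length(el)
  pn <- c(eb, el)
  out <- vector("list", nd)
  for (d in seq_len(nd)) {
    Ld <- vapply(L, function(m) m[d, ], numeric(nt))
    f0d <- f0[d, ]
    V <- Ld %*% (om * t(Ld)) + diag(sp * f0d^2 + sa, nrow = nt)
    ch <- tryCatch(chol((V + t(V)) / 2), error = function(e) NULL)
    if (is.null(ch)) { out[[d]] <- NULL; next }
    Vi <- chol2inv(ch)
    Md <- vapply(M, function(m) m[d, ], numeric(nt))
    # dV/dlambda is exact here: V is linear in the variance parameters
    dV <- lapply(el, function(p) {
      switch(p,
             omega2_emax = tcrossprod(Ld[, "emax"]),
             omega2_ec50 = tcrossprod(Ld[, "ec50"]),
             omega2_cl = tcrossprod(Ld[, "cl"]),
             omega2_v = tcrossprod(Ld[, "v"]),
             sigma2_add = diag(nt),
             sigma2_prop = diag(f0d^2, nrow = nt))
    })
    Fm <- matrix(0, nb + nl, nb + nl, dimnames = list(pn, pn))
    Fm[seq_len(nb), seq_len(nb)] <- t(Md) %*% Vi %*% Md
    for (a in seq_len(nl)) {
      for (b in a:nl) {
        tr <- sum((Vi %*% dV[[a]] %*% Vi) * dV[[b]]) / 2
        Fm[nb + a, nb + b] <- Fm[nb + b, nb + a] <- tr
      }
    }
    out[[d]] <- (Fm + t(Fm)) / 2
  }
  out
}
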