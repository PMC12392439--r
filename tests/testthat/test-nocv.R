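# NOCV eigenpairs, channel pairing, channel energies and densities.

test_that("2x2 analytic case: eigenvalues, valence, channel energy by hand", {
  # adduct orbital (1,1)/sqrt(2) doubly occupied, promolecule orbital (1,0)
  # doubly occupied, orthonormal AO basis
  P <- matrix(c(1, 1, 1, 1), 2)
  P0 <- matrix(c(2, 0, 0, 0), 2)
  dP <- P - P0
  eig <- nocv_eigenpairs(dP, diag(2))
  expect_equal(eig$values, c(sqrt(2), -sqrt(2)), tolerance = 1e-12)
  expect_equal(total_valence(P, dP, diag(2)), 2, tolerance = 1e-12)
  # eigenvectors are normalized and phase-fixed
  expect_equal(colSums(eig$vectors^2), c(1, 1), tolerance = 1e-12)
  expect_true(all(apply(abs(eig$vectors), 2, max) ==
                    apply(eig$vectors, 2, max)))
  # one channel; with a diagonal F~ the channel energy follows by hand:
  # dE_1 = v (c+' F c+ - c-' F c-)
  ch <- pair_channels(eig)$channels
  expect_length(ch, 1)
  expect_equal(ch[[1]]$v, sqrt(2), tolerance = 1e-12)
  Ft <- diag(c(-0.3, 0.1))
  withE <- channel_energies(ch, Ft)
  cp <- ch[[1]]$c_plus; cm <- ch[[1]]$c_minus
  hand <- sqrt(2) * (drop(crossprod(cp, Ft %*% cp)) -
                       drop(crossprod(cm, Ft %*% cm)))
  expect_equal(withE[[1]]$dE, hand, tolerance = 1e-12)
  # and the sum over the full (single) pair equals Tr{F~ dP}
  expect_equal(hand, sum(Ft * dP), tolerance = 1e-12)
})

test_that("zero deformation gives an all-zero spectrum and V = 0", {
  S <- diag(3)
  eig <- nocv_eigenpairs(matrix(0, 3, 3), S)
  expect_equal(eig$values, rep(0, 3))
  expect_identical(total_valence(matrix(0, 3, 3), matrix(0, 3, 3), S), 0)
})

test_that("particle conservation: eigenvalues sum to zero", {
  eda <- water2_eda()
  dP <- eda$scf$AB$P - eda$promolecule$P0
  eig <- nocv_eigenpairs(dP, eda$ints)
  expect_lt(abs(sum(eig$values)), 1e-10)
  expect_lt(abs(sum(dP * eda$ints$S)), 1e-10)
})

test_that("eigenpairs match a dense brute-force diagonalization on a small fixture", {
  eda <- heh_eda()   # 2 AOs
  dP <- eda$scf$AB$P - eda$promolecule$P0
  S <- eda$ints$S
  es <- eigen(S, symmetric = TRUE)
  Sh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  ref <- sort(eigen(Sh %*% dP %*% Sh, symmetric = TRUE)$values,
              decreasing = TRUE)
  eig <- nocv_eigenpairs(dP, eda$ints)
  expect_equal(eig$values, ref, tolerance = 1e-10)
  # S-normalization of the back-transformed vectors
  G <- crossprod(eig$vectors, S %*% eig$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-10)
})

test_that("restricted idempotent inputs pair exactly and degeneracies are preserved", {
  eda <- arli_eda()
  dP <- eda$scf$AB$P - eda$promolecule$P0
  eig <- nocv_eigenpairs(dP, eda$ints)
  pr <- pair_channels(eig, cutoff = 1e-6)
  for (ch in pr$channels) {
    # every significant +v has a -v partner matching to 1e-7
    neg <- eig$values[which.min(abs(eig$values + ch$v))]
    expect_lt(abs(ch$v + neg), 1e-7)
  }
  # the pi channels of Ar-Li+ are doubly degenerate and reported separately
  vs <- vapply(pr$channels, `[[`, numeric(1), "v")
  pis <- vs[2:3]
  expect_lt(abs(pis[1] - pis[2]), 1e-7)
})

test_that("cutoff behavior: everything below cutoff leaves an empty list with diagnostics", {
  eda <- heh_eda()
  dP <- eda$scf$AB$P - eda$promolecule$P0
  eig <- nocv_eigenpairs(dP, eda$ints)
  pr <- pair_channels(eig, cutoff = 10)
  expect_length(pr$channels, 0)
  expect_equal(pr$diagnostics$subcutoff_weight, sum(abs(eig$values)),
               tolerance = 1e-12)
})

test_that("channel-energy sum reproduces the transition-state trace", {
  for (eda in list(water2_eda(), hf2_eda(), arli_eda())) {
    res <- nocv_channels(eda, cutoff = 0)
    expect_lt(abs(res$residual), 1e-10)
    expect_equal(res$channel_sum, res$trace_ref, tolerance = 1e-10)
    expect_equal(res$trace_ref, eda$terms$dE_orb_ets2, tolerance = 1e-12)
  }
})

test_that("total valence is invariant under the orthogonal representation used", {
  eda <- water2_eda()
  P <- eda$scf$AB$P; dP <- P - eda$promolecule$P0; S <- eda$ints$S
  v1 <- total_valence(P, dP, S)
  # canonical orthogonalization instead of Loewdin
  es <- eigen(S, symmetric = TRUE)
  Xc <- es$vectors %*% diag(1 / sqrt(es$values))
  Pc <- t(Xc) %*% S %*% P %*% S %*% Xc
  dPc <- t(Xc) %*% S %*% dP %*% S %*% Xc
  expect_equal(v1, sum(Pc * t(dPc)), tolerance = 1e-10)
})

test_that("channel densities integrate to zero and sum to the direct deformation density", {
  eda <- heh_eda()
  res <- nocv_channels(eda, cutoff = 0)
  gs <- default_grid(eda$system$adduct, padding = 7, spacing = 0.15)
  cd <- channel_density(res, eda, gs)
  for (f in cd$channels) expect_lt(abs(field_integral(f)), 1e-4)
  direct <- density_on_grid(eda$scf$AB$P - eda$promolecule$P0, eda$ints, gs)
  expect_lt(max(abs(cd$total - direct)), 1e-8)
})

test_that("dominant water-dimer channel accumulates density in the hydrogen bond", {
  eda <- water2_eda()
  res <- nocv_channels(eda)
  # midpoint between donating H (atom 2) and acceptor O (atom 4)
  mid <- (eda$system$adduct$xyz[2, ] + eda$system$adduct$xyz[4, ]) / 2
  gs <- grid_spec(mid - 0.1, diag(0.1, 3), c(3, 3, 3))
  cd <- channel_density(res, eda, gs, channels = 1)
  expect_gt(mean(cd$channels[[1]]), 0)
})

test_that("spin-resolved analysis of a closed-shell system reproduces the restricted one", {
  sys <- make_fixture("water2")
  eu <- decompose(sys, nocv_method(force_unrestricted = TRUE))
  er <- water2_eda()
  ru <- nocv_channels(eu); rr <- nocv_channels(er)
  expect_equal(ru$trace_ref, rr$trace_ref, tolerance = 1e-6)
  # alpha and beta channel lists coincide
  va <- vapply(ru$per_spin$alpha$channels, `[[`, numeric(1), "v")
  vb <- vapply(ru$per_spin$beta$channels, `[[`, numeric(1), "v")
  expect_equal(va, vb, tolerance = 1e-6)
  # restricted occupancy-2 eigenvalues are twice the per-spin ones
  vr <- vapply(rr$channels, `[[`, numeric(1), "v")
  expect_equal(unname(vr[seq_along(va)]), unname(2 * va), tolerance = 1e-5)
})

test_that("sigma-bond formation from two doublets gives one channel per spin with the rank-1 closed form", {
  sys <- make_fixture("h2_from_atoms", R = 1.4 / BOHR)
  eda <- decompose(sys)
  res <- nocv_channels(eda)
  expect_length(res$channels, 2)
  expect_setequal(vapply(res$channels, `[[`, character(1), "spin"),
                  c("alpha", "beta"))
  # rank-1 projector oracle: dP^sigma = psi psi' - phi phi' (Loewdin basis)
  # has eigenvalues +-sqrt(1 - c^2) with c the orbital overlap
  scf <- eda$scf$AB; pm <- eda$promolecule; S <- eda$ints$S
  psi <- scf$C$a[, 1]                      # adduct alpha spin-orbital
  phi <- pm$C0$a[, 1]                      # promolecule alpha spin-orbital
  c2 <- drop(crossprod(psi, S %*% phi))^2
  expect_equal(res$channels[[1]]$v, sqrt(1 - c2), tolerance = 1e-8)
  # dense diagonalization of the explicitly constructed spin block
  es <- eigen(S, symmetric = TRUE)
  Sh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  M <- Sh %*% (scf$Pa - pm$P0a) %*% Sh
  ref <- max(eigen(M, symmetric = TRUE)$values)
  expect_equal(res$channels[[1]]$v, ref, tolerance = 1e-10)
  # spin channels together recover the orbital term
  expect_equal(res$channel_sum, eda$terms$dE_orb_ets2, tolerance = 1e-9)
})

test_that("spin deformation densities add to the total on the grid", {
  sys <- make_fixture("h2_from_atoms")
  eda <- decompose(sys)
  gs <- default_grid(sys$adduct, padding = 5, spacing = 0.25)
  dPa <- eda$scf$AB$Pa - eda$promolecule$P0a
  dPb <- eda$scf$AB$Pb - eda$promolecule$P0b
  fa <- density_on_grid(dPa, eda$ints, gs)
  fb <- density_on_grid(dPb, eda$ints, gs)
  ftot <- density_on_grid(dPa + dPb, eda$ints, gs)
  expect_lt(max(abs(fa + fb - ftot)), 1e-10)
})

test_that("double-hybrid split: zero-coefficient limit and trace-free MP2 correction field", {
  # a_C = 0: correction density identically zero
  eda0 <- decompose(make_fixture("heh+"), nocv_method("hf+mp2", mp2_coefficient = 0))
  sp0 <- dh_density_split(eda0)
  expect_true(all(sp0$D_mp2_delta == 0))
  expect_identical(sp0$dE_mp2, 0)
  # a_C > 0: the NOCV analysis still runs on the idempotent SCF part,
  # and the MP2 difference-density field integrates to zero
  m <- nocv_method("hf+mp2", mp2_coefficient = 0.27)
  eda <- decompose(make_fixture("heh+"), m)
  sp <- dh_density_split(eda)
  expect_lt(abs(sum(sp$D_mp2_delta * eda$ints$S)), 1e-8)
  gs <- default_grid(eda$system$adduct, padding = 7, spacing = 0.15)
  f <- density_on_grid(sp$D_mp2_delta, eda$ints, gs)
  expect_lt(abs(field_integral(f)), 1e-4)
  res <- nocv_channels(eda, cutoff = 0)
  expect_lt(abs(res$residual), 1e-10)     # pairing preserved on the SCF part
})

test_that("homodimer channel fields respect fragment-exchange symmetry", {
  eda <- decompose(make_fixture("be2"))
  res <- nocv_channels(eda)
  sys <- eda$system
  mid <- (sys$adduct$xyz[1, 3] + sys$adduct$xyz[2, 3]) / 2
  gs <- grid_spec(c(-2, -2, mid - 3), diag(c(0.5, 0.5, 0.5)), c(9, 9, 13))
  cd <- channel_density(res, eda, gs, channels = 1)
  f <- array(cd$channels[[1]], dim = rev(gs$counts))   # z fastest
  # mirror in the z = mid plane maps the field onto itself
  expect_lt(max(abs(f - f[rev(seq_len(dim(f)[1])), , ])), 1e-6)
})
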