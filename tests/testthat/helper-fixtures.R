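# Shared fixtures, memoized so expensive decompositions run once per suite.
KCAL <- 627.5094740631
BOHR <- 1 / 0.529177210903

.memo <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

water2_eda <- function() memo("water2_eda", decompose(make_fixture("water2")))
hf2_eda <- function() memo("hf2_eda", decompose(make_fixture("hf2")))
heh_eda <- function() memo("heh_eda", decompose(make_fixture("heh+")))
arli_eda <- function() memo("arli_eda", decompose(make_fixture("arli+")))

# independent Fock/energy assembly by explicit loops over the ERI tensor
# (oracle path: no use of the production coulomb/exchange matrix builders)
loop_fock_energy <- function(ints, Pa, Pb) {
  n <- ints$n
  eri <- array(ints$eri, rep(n, 4))
  J <- matrix(0, n, n); Ka <- matrix(0, n, n); Kb <- matrix(0, n, n)
  P <- Pa + Pb
  for (mu in 1:n) for (nu in 1:n) for (la in 1:n) for (si in 1:n) {
    J[mu, nu] <- J[mu, nu] + eri[mu, nu, la, si] * P[la, si]
    Ka[mu, nu] <- Ka[mu, nu] + eri[mu, la, nu, si] * Pa[la, si]
    Kb[mu, nu] <- Kb[mu, nu] + eri[mu, la, nu, si] * Pb[la, si]
  }
  E <- sum(ints$hcore * P) + 0.5 * sum(J * P) -
    0.5 * (sum(Ka * Pa) + sum(Kb * Pb)) + ints$enuc
  list(E = E, Fa = ints$hcore + J - Ka, Fb = ints$hcore + J - Kb)
}
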