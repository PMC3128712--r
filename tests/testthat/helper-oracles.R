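# Shared fixtures and independent oracles, all built in code.

# ---- tiny alignment / cohort fixtures -------------------------------------

tiny_alignment_text <- function() {
  paste(
    "# two-allele toy alignment",
    "allele\t1\t2\t3",
    "A*01:01\tN\tS\tY",
    "A*02:01\t-\t-\tF",
    sep = "\n")
}

toy_cohort <- function() {
  cohort_genotypes(
    sample_id = c("s1", "s2", "s3", "s4"),
    status = c(1, 1, 0, 0),
    allele1 = c("DRB1*03:01", "DRB1*03:01", "DRB1*13:02", "DRB1*15:01"),
    allele2 = c("DRB1*03:01", "DRB1*13:01", "DRB1*04:01", "DRB1*01:01"))
}

# ---- logistic regression oracles ------------------------------------------

# brute-force profile of the two-parameter Bernoulli log-likelihood over a
# successively refined grid; independent of the IRLS code path
grid_logistic_oracle <- function(x, y) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ctr <- c(0, 0)
  hw <- 8
  step <- 0.1
  for (stage in 1:4) {
    b0s <- seq(ctr[1] - hw, ctr[1] + hw, by = step)
    b1s <- seq(ctr[2] - hw, ctr[2] + hw, by = step)
    L <- outer(b0s, b1s, Vectorize(ll))
    ix <- which(L == max(L), arr.ind = TRUE)[1L, ]
    ctr <- c(b0s[ix[1L]], b1s[ix[2L]])
    hw <- 2 * step
    step <- step / 10
  }
  ctr
}

# fixed suite of 8-sample designs with one binary covariate, none separated
toy_logistic_designs <- function() {
  list(
    list(x = c(0, 0, 0, 0, 1, 1, 1, 1), y = c(0, 0, 0, 1, 0, 1, 1, 1)),
    list(x = c(0, 0, 1, 1, 0, 0, 1, 1), y = c(0, 1, 0, 1, 1, 0, 1, 1)),
    list(x = c(0, 1, 0, 1, 0, 1, 0, 1), y = c(1, 0, 0, 1, 0, 1, 1, 0)),
    list(x = c(0, 0, 0, 1, 1, 1, 1, 1), y = c(0, 1, 0, 0, 1, 1, 0, 1)))
}

# ---- electrostatics oracles -----------------------------------------------

# Coulomb constant recomputed from SI constants (not from the package)
coulomb_kt_si <- function(temperature = 298.15) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23
  # e^2/(4 pi eps0 kT) in metres, converted to Angstrom
  e^2 / (4 * pi * eps0 * kb * temperature) * 1e10
}

# inverse Debye length (1/Angstrom) from SI constants for a 1:1 electrolyte
kappa_si <- function(ionic_strength, eps_s = 80, temperature = 298.15) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23
  na <- 6.02214076e23
  n <- 2 * ionic_strength * 1000 * na          # ions per m^3
  sqrt(n * e^2 / (eps0 * eps_s * kb * temperature)) * 1e-10
}

# exact piecewise solution for a Born ion: charge q at the centre of a
# sphere of radius `radius` (interior dielectric eps_i), probe-inflated
# dielectric boundary at radius+probe, ion exclusion to radius+stern,
# screened solvent beyond
born_analytic <- function(r, q = 1, radius = 2, eps_i = 2, eps_s = 80,
                          probe = 1.4, stern = 2, ionic_strength = 0.145,
                          temperature = 298.15) {
  C <- coulomb_kt_si(temperature)
  b <- radius + probe
  a <- radius + stern
  kap <- kappa_si(ionic_strength, eps_s, temperature)
  B <- -C * q / eps_s * kap / (1 + kap * a)
  A <- C * q / (eps_s * b) + B - C * q / (eps_i * b)
  out <- numeric(length(r))
  inner <- r <= b
  mid <- r > b & r <= a
  outer_ <- r > a
  out[inner] <- C * q / (eps_i * r[inner]) + A
  out[mid] <- C * q / (eps_s * r[mid]) + B
  out[outer_] <- C * q / eps_s * exp(-kap * (r[outer_] - a)) /
    ((1 + kap * a) * r[outer_])
  out
}

null_demo_spec <- function(seed, ...) {
  psc_demo_spec(seed, effects = data.frame(position = integer(0),
                                           amino = character(0),
                                           beta = numeric(0)), ...)
}
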