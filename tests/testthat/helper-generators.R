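# Shared test helpers: random classification objects for round-trip
# properties, random involvement sets, and the independent hypergeometric
# enumeration oracle for the Fisher test.

vocab <- subsite_vocabulary()

random_involvements <- function(p = 0.25) {
  sel <- which(runif(nrow(vocab)) < p)
  if (length(sel) == 0L) return(thyrostage:::empty_involvements())
  inv <- do.call(rbind, lapply(sel, function(i) {
    involvement(
      vocab$category[i], vocab$code[i],
      degree = if (vocab$takes_degree[i]) sample(0:1, 1) else NA,
      rings = if (vocab$takes_ring_count[i] && runif(1) < 0.7) {
        sample(1:5, 1)
      } else NA
    )
  }))
  inv
}

# a random valid parsed classification (never empty: at least a TNM, the
# Rec prefix, or one involvement)
random_parsed <- function() {
  repeat {
    rec <- runif(1) < 0.3
    inv <- random_involvements()
    tnm <- if (!rec && runif(1) < 0.9) {
      list(t = sample(c("TX", "T0", "T1a", "T1b", "T2", "T3a", "T3b",
                        "T4a", "T4b"), 1),
           n = sample(c("NX", "N0", "N0a", "N0b", "N1", "N1a", "N1b"), 1),
           m = sample(c("MX", "M0", "M1"), 1))
    } else NULL
    if (rec || !is.null(tnm) || nrow(inv) > 0L) {
      return(classification(rec = rec,
                            residual = sample(c("R0", "R1", "R2"), 1,
                                              prob = c(0.7, 0.15, 0.15)),
                            tnm = tnm, involvements = inv))
    }
  }
}

# independent two-tailed Fisher oracle: hypergeometric masses via
# stats::dhyper, summing all masses not exceeding the observed one
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(x, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

primary_cases <- function(cases) {
  Filter(function(cs) cs$record$mds$disease_status == "primary", cases)
}

recurrent_cases <- function(cases) {
  Filter(function(cs) cs$record$mds$disease_status != "primary", cases)
}

tally_of <- function(tallies, class) {
  tallies$cases[tallies$class == class]
}
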