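# Independent oracles and memoized fixtures shared across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_benchmark <- function(n = 12, seed = 101, withhold = 0) {
  memo(sprintf("bench_%d_%d_%s", n, seed, withhold),
       suppressMessages(make_benchmark(n, seed = seed,
                                       withhold_fraction = withhold)))
}

test_reaction_pairs <- function(seed = 7) {
  memo(sprintf("pairs_%d", seed),
       suppressMessages(make_reaction_pairs(seed = seed)))
}

# ---- exhaustive modified-cosine oracle -------------------------------------
# Enumerates every one-to-one peak pairing over the candidate (direct or
# shifted) pairs and takes the maximum cosine; independent of the bipartite
# matching used by the implementation.  Only feasible for small spectra.
oracle_modified_cosine <- function(a, b, fragment_tol = 0.02) {
  norm_w <- function(s) {
    w <- sqrt(s$peaks[, "intensity"])
    n <- sqrt(sum(w^2))
    if (n == 0) w else w / n
  }
  wa <- norm_w(a)
  wb <- norm_w(b)
  mza <- a$peaks[, "mz"]
  mzb <- b$peaks[, "mz"]
  delta <- neutral_mass(b) - neutral_mass(a)
  ok <- abs(outer(mza, mzb, "-")) <= fragment_tol |
    abs(outer(mza + delta, mzb, "-")) <= fragment_tol
  best <- 0
  recurse <- function(i, used, acc) {
    if (acc > best) best <<- acc
    if (i > length(mza)) return(invisible(NULL))
    recurse(i + 1L, used, acc)                    # leave peak i unmatched
    for (j in seq_along(mzb)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + wa[i] * wb[j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(mzb)), 0)
  min(1, best)
}

# random spectra with engineered overlap: b borrows peaks from a, some
# shifted by the precursor difference, plus noise peaks on both sides
random_spectrum_pair <- function(max_peaks = 8) {
  n_a <- sample(2:max_peaks, 1)
  mza <- sort(round(runif(n_a, 60, 480), 3))
  pa <- round(runif(1, 500, 520), 3)
  delta <- round(runif(1, -60, 60), 3)
  n_shared <- sample(0:n_a, 1)
  shared <- if (n_shared > 0) sample(mza, n_shared) else numeric(0)
  is_shift <- runif(n_shared) < 0.5
  mzb <- c(shared[!is_shift], shared[is_shift] + delta,
           runif(sample(0:3, 1), 60, 480))
  mzb <- mzb[mzb > 10]
  if (length(mzb) == 0) mzb <- runif(1, 60, 480)
  mzb <- sort(round(mzb + sample(c(0, 0.005, -0.005),
                                 length(mzb), replace = TRUE), 3))
  mzb <- mzb[!duplicated(mzb)][seq_len(min(length(mzb), max_peaks))]
  a <- spectrum("a", pa, cbind(mza, round(runif(n_a, 0.05, 1), 3)))
  b <- spectrum("b", pa + delta, cbind(mzb, round(runif(length(mzb), 0.05, 1), 3)))
  list(a = a, b = b)
}

# ---- per-atom mass summation oracle ----------------------------------------
# Monoisotopic mass from the molecular formula and a standard element mass
# table; independent of the mass computed by the chemistry backend.
ELEMENT_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183371, I = 126.904473, Na = 22.9897692809)

formula_mass <- function(formula) {
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  total <- 0
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", t)))
    if (is.na(n)) n <- 1L
    if (is.na(ELEMENT_MASS[el])) stop("element not in oracle table: ", el)
    total <- total + n * ELEMENT_MASS[[el]]
  }
  total
}

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}
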