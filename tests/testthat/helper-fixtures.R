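# Shared small fixtures, built in code at test time.

# three-population profile set for annotation / DE tests
small_profiles <- function(effect = 8, seed = 11) {
  make_population_profiles(n_genes = 600, populations = c("A", "B", "C"),
                           markers_per_pop = 30, effect_size = effect,
                           baseline_mean = 1, seed = seed)
}

# hand-built six-cell matrix: one cell violating each QC rule + one clean
# cell + one boundary cell. 400 genes incl. 4 mito genes.
qc_fixture <- function() {
  n_genes <- 404
  genes <- c(sprintf("MT-%02d", 1:4), sprintf("G%03d", 5:n_genes))
  m <- matrix(0L, nrow = n_genes, ncol = 6,
              dimnames = list(genes, sprintf("C%d", 1:6)))
  # C1: 299 genes detected (fewer than 300) -> removed
  m[5:303, 1] <- 3L                                  # 299 genes, 897 counts
  # C2: 450 total counts (falling below 500) -> removed
  m[5:304, 2] <- 1L; m[5:154, 2] <- 2L               # 300 genes, 450 counts
  # C3: 30050 counts (exceeding 30000) -> removed
  m[5:304, 3] <- 100L; m[5, 3] <- 150L               # 300 genes, 30050
  # C4: 12% mito (exceeding 10%) -> removed
  m[5:304, 4] <- 2L; m[1:4, 4] <- c(21L, 21L, 21L, 21L)  # 84/684 = 12.3%
  # C5: clean cell
  m[5:404, 5] <- 2L                                  # 400 genes, 800 counts
  # C6: exactly on every boundary -> retained
  m[5:302, 6] <- 1L                                  # 298 genes so far
  m[304, 6] <- 152L                                  # 299 genes, 450 counts
  m[1, 6] <- 50L                                     # 300 genes, 500 counts, mito 10%
  gexp(m)
}

# expand a junction with realistic flank lengths
fixture_junction <- function(k = 12, name = "PML-RARA-L") {
  build_junction_kmer(
    upstream_flank = "TCCGAATGGCAGGTCGATCCGGAACTGCAGG",
    downstream_flank = "TCAGTGGATCCGAGGCTTACGGATCAGCTAA",
    k = k, name = name)
}

# brute-force log-rank chi-square oracle: independent implementation
# accumulating O/E/V from explicit risk-set tables
logrank_oracle <- function(time, event, g1) {
  stopifnot(length(time) <= 400)
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    died <- which(time == t & event == 1)
    n <- length(risk); n1 <- sum(g1[risk]); d <- length(died)
    O <- O + sum(g1[died])
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# brute-force Benjamini-Hochberg
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}
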