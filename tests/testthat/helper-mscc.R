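# Shared fixture builders. Everything is generated in code under fixed
# seeds; expensive simulations are cached per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (!exists(name, envir = .sim_cache)) assign(name, fun(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

# A small complete simulation: genome, annotations, sites, truth (null).
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- simulation_config(seed = 101, n_chroms = 2, chrom_length = 50000)
    gen <- generate_genome(cfg)
    sites <- find_ccgg_sites(gen$genome)
    truth <- generate_methylome(gen$genome, gen$annotations, cfg)
    list(cfg = cfg, genome = gen$genome, ann = gen$annotations,
         sites = sites, truth = truth)
  })
}

# Truth for the baseline sample as a call-shaped table (level = truth).
truth_as_calls <- function(sim, sample_label = "S0h") {
  out <- sim$truth[sim$truth$sample == sample_label, ]
  out$u <- 0L
  out$m <- 0L
  out$depth <- 1000L
  out
}

# Random DNA of length n under a local seed.
random_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Reverse complement without package internals (test-side oracle).
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Brute-force distance of each site to the nearest interval base (0 when
# inside, Inf when the chromosome carries no interval).
interval_distance_oracle <- function(sites, intervals) {
  vapply(seq_len(nrow(sites)), function(i) {
    iv <- intervals[intervals$chrom == sites$chrom[i], ]
    if (nrow(iv) == 0) return(Inf)
    p <- sites$pos[i]
    min(pmax(iv$start - p, p - (iv$end - 1), 0))
  }, numeric(1))
}

# Brute-force two-sided Fisher p via explicit combinatorial enumeration of
# all tables with the observed margins (independent of dhyper).
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  tab_prob <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  }
  probs <- vapply(xs, tab_prob, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
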