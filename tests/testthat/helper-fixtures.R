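# Shared fixtures, built in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small planted world reused across module tests
small_world <- function() memo("small_world",
  generate_genome_and_elements(101, n_chroms = 2L, chrom_len = 2e5,
                               n_elements = 400L, element_len = 300L))

# deterministic 4-column PWM helper: columns are one-hot for the given bases
pwm_from_consensus <- function(cons, p = 1) {
  bases <- strsplit(cons, "")[[1]]
  L <- length(bases)
  m <- matrix((1 - p) / 3, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_len(L))] <- p
  m
}

# dense per-base oracle for track operations over one chromosome
dense_track <- function(track, chrom, len) {
  r <- track[[chrom]]
  v <- as.numeric(r)
  if (length(v) < len) v <- c(v, rep(0, len - length(v)))
  v[seq_len(len)]
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  n <- nchar(s)
  table(substring(s, 1:(n - 1), 2:n))
}

random_track <- function(chrom, len, n_runs, seed) {
  set.seed(seed)
  cuts <- sort(sample.int(len - 1L, n_runs - 1L))
  start0 <- c(0L, cuts)
  end <- c(cuts, len)
  keep <- sample(c(TRUE, FALSE), n_runs, replace = TRUE)
  vals <- ifelse(keep, round(runif(n_runs, 0, 5), 3), 0)
  signal_track(rep(chrom, n_runs), start0, end, vals,
               seqlengths = setNames(len, chrom))
}
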