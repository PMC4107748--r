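# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`; NULL leaves the
# ambient RNG untouched. Restores .Random.seed afterwards so callers' streams
# are not perturbed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31-1).
# Used to derive per-well seeds from (sample, replicate) labels so a plate is
# reproducible from one master seed without per-well bookkeeping.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, sample_id, replicate) {
  key <- paste(sample_id, replicate, sep = "|")
  as.integer((as.numeric(master_seed) + stable_hash(key)) %% 2147483646) + 1L
}

# one-decimal percentage, the reporting convention used throughout
pct1 <- function(num, den) round(100 * num / den, 1)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

stop_ddcnv <- function(msg, class) {
  stop(structure(
    class = c(class, "ddcnv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
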