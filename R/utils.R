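# Internal helpers: named RNG streams, chromosome-name normalisation,
# classed errors for the CLI, and a small config checksum.

# One root seed is split into independent named streams so that, e.g.,
# adding variants never perturbs the exposure draws. The derived seed is a
# deterministic 31-bit mix of the root seed and the stream name.
.streamSeed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483629
  s <- as.double(seed) %% 2147483629
  s <- (s * 48271) %% 2147483629
  as.integer((s + h * 69621) %% 2147483629)
}

.withStream <- function(seed, stream, expr) {
  set.seed(.streamSeed(seed, stream))
  expr
}

.normChrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

.configError <- function(msg) {
  stop(structure(class = c("ageGWIS_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.dataError <- function(msg) {
  stop(structure(class = c("ageGWIS_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Polynomial checksum of a deparsed object; used to stamp run artifacts.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.z975 <- function() qnorm(0.975)
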