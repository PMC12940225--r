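# internal helpers shared across modules

# Deterministic substream seed: every output artifact draws from its own
# stream derived from (master seed, stream name), so adding a new artifact
# never perturbs existing ones. Plain polynomial string hash, kept below 2^31.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# canonical taxon name: lowercase, runs of non-alphanumerics collapsed to "_"
canonical_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# z-standardize, guarding constant input
zstd <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant column")
  (x - mean(x, na.rm = TRUE)) / s
}

round6 <- function(x) round(x, 6L)

abort_gf <- function(msg, class) {
  rlang::abort(msg, class = paste0("gutfluxr_", class))
}

warn_gf <- function(msg, class) {
  rlang::warn(msg, class = paste0("gutfluxr_", class))
}
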