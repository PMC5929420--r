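# Internal helpers: classed error conditions and a small provenance hash.

.fwError <- function(msg, class) {
  stop(structure(
    class = c(class, "fluxwindowError", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

.validationError <- function(msg) .fwError(msg, "fw_validation_error")
.formatError     <- function(msg) .fwError(msg, "fw_format_error")
.configError     <- function(msg) .fwError(msg, "fw_config_error")
.ioError         <- function(msg) .fwError(msg, "fw_io_error")
.contractError   <- function(msg) .fwError(msg, "fw_contract_error")
.usageError      <- function(msg) .fwError(msg, "fw_usage_error")

# FNV-1a 32-bit hash of a character scalar; provenance stamp for output headers,
# not cryptographic.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in 16-bit halves to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.hashFile <- function(path) {
  .fnv1a(readChar(path, file.info(path)$size, useBytes = TRUE))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.fmtNum <- function(x) sprintf("%.17g", x)
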