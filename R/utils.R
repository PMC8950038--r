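# Internal helpers: classed error conditions and small shared utilities.

abort_aswnet <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "aswnet_error", "error")))
}

err_not_found       <- function(msg) abort_aswnet(msg, "aswnet_not_found")
err_unsupported     <- function(msg) abort_aswnet(msg, "aswnet_unsupported_format")
err_io              <- function(msg) abort_aswnet(msg, "aswnet_io_failure")
err_shape           <- function(msg) abort_aswnet(msg, "aswnet_shape_error")
err_missing_class   <- function(msg) abort_aswnet(msg, "aswnet_missing_class")
err_empty_dataset   <- function(msg) abort_aswnet(msg, "aswnet_empty_dataset")
err_divergence      <- function(msg) abort_aswnet(msg, "aswnet_divergence")
err_insufficient    <- function(msg) abort_aswnet(msg, "aswnet_insufficient_pairs")
err_manifest        <- function(msg) abort_aswnet(msg, "aswnet_manifest_error")
err_unknown_layer   <- function(msg) abort_aswnet(msg, "aswnet_unknown_layer")

# Deterministic child seed derivation, kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 69621) %% 2147483587)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
}
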