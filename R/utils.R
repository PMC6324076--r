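# Internal helpers shared across modules.

# Stable identifier for the reference a store was built against; merging or
# comparing stores across different references is refused.
assembly_tag <- function(reference) {
  ref <- dplyr::arrange(reference, .data$transcript_id)
  rlang::hash(list(ref$transcript_id, ref$length, ref$cds_start, ref$cds_stop))
}

stopifnot_reference <- function(reference, arg = "reference") {
  if (!inherits(reference, "ribo_reference")) {
    abort(sprintf("`%s` must be a `ribo_reference` (see `read_reference()`).", arg))
  }
  invisible(reference)
}

# 1-based frame of a transcript position: (pos - 1) mod 3.
position_frame <- function(position) (position - 1L) %% 3L

match_arg2 <- function(arg, choices) {
  arg <- arg[1]
  if (!arg %in% choices) {
    abort(sprintf(
      "Invalid value '%s'; must be one of %s.",
      arg, paste(sprintf("'%s'", choices), collapse = ", ")
    ))
  }
  arg
}
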