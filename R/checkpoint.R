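# Model checkpoints: versioned JSON archives holding the architecture spec
# and parameter arrays. A checkpoint is the only artifact that crosses the
# study boundary — the privacy mechanism rests on sharing it instead of data.

CHECKPOINT_FORMAT <- "lapsenet-checkpoint-1"

#' Save an adherence network to a JSON checkpoint
#'
#' Values are written at full precision, so a save/load round trip
#' reproduces predictions bit-for-bit.
#'
#' @param net An `adherence_net`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
save_checkpoint <- function(net, file) {
  stopifnot(inherits(net, "adherence_net"))
  s <- net$spec
  payload <- list(
    format = CHECKPOINT_FORMAT,
    spec = list(window_size = s$window_size, in_channels = s$in_channels,
                conv_channels = s$conv_channels, kernel_sizes = s$kernel_sizes,
                pool_sizes = s$pool_sizes, hidden_units = s$hidden_units,
                n_classes = s$n_classes, seed = s$seed),
    params = lapply(net$params, function(p) {
      # 17 significant digits guarantee an exact double round trip; values
      # travel as strings so no JSON number formatting can touch them
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           values = sprintf("%.17g", as.numeric(p)))
    })
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Load an adherence network from a JSON checkpoint
#'
#' @param file Checkpoint path written by [save_checkpoint()].
#' @return An `adherence_net`.
#' @export
load_checkpoint <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(payload$format, CHECKPOINT_FORMAT)) {
    stop("not a recognized checkpoint file: ", file, call. = FALSE)
  }
  sp <- payload$spec
  spec <- adherence_net_spec(
    window_size = sp$window_size, in_channels = sp$in_channels,
    conv_channels = sp$conv_channels, kernel_sizes = sp$kernel_sizes,
    pool_sizes = sp$pool_sizes, hidden_units = sp$hidden_units,
    n_classes = sp$n_classes, seed = sp$seed
  )
  params <- lapply(payload$params, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
  })
  names(params) <- names(payload$params)
  structure(list(spec = spec, params = params), class = "adherence_net")
}
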