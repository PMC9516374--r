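# Internal helpers: logging, clipping, seed derivation.

qc_log_level <- function() {
  lv <- getOption("qcoach.log_level", "info")
  match.arg(lv, c("debug", "info", "warn", "quiet"))
}

#' @noRd
qc_log <- function(..., level = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] < ranks[[qc_log_level()]]) return(invisible(NULL))
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
  message(msg)
  invisible(NULL)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Derive a component seed from a global seed
#'
#' A fixed, documented derivation so each pipeline component is individually
#' reproducible from one global seed. Result is always in [1, 2^31 - 2].
#'
#' @param seed integer global seed.
#' @param component character label of the component.
#' @return integer seed.
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(component))
  offset <- sum(utf8ToInt(component))
  as.integer((abs(seed) * 48271 + offset * 7919) %% (2^31 - 1) + 1)
}

# write `lines`/object atomically: temp file in same dir, then rename
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic write failed for ", path)
  invisible(path)
}
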