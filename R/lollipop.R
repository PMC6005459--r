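## Text lollipop rendering of a methylation call matrix: one row per read,
## one column per CpG, symbols for methylated / unmethylated / missing.
## TSV form round-trips losslessly to and from the call matrix.

LOLLIPOP_SYMBOLS <- c(methylated = "*", unmethylated = "o", missing = ".")

#' Render a methylation call matrix as a text lollipop grid
#'
#' Reads are sorted densest-first (descending methylated fraction, stable).
#' `*` = methylated, `o` = unmethylated, `.` = missing.
#'
#' @param m A [methylation_call_matrix()].
#' @return Character vector of lines (header plus one line per read).
#' @export
render_lollipop <- function(m) {
  stopifnot(inherits(m, "methylation_call_matrix"))
  header <- paste(c("read_id", as.character(m$cpg_sites)), collapse = "\t")
  if (nrow(m$calls) == 0) return(header)
  ord <- order(-rowMeans(m$calls, na.rm = TRUE))
  sym <- matrix(LOLLIPOP_SYMBOLS["missing"], nrow(m$calls), ncol(m$calls))
  sym[m$calls == 1] <- LOLLIPOP_SYMBOLS["methylated"]
  sym[m$calls == 0] <- LOLLIPOP_SYMBOLS["unmethylated"]
  body <- vapply(ord, function(i)
    paste(c(m$read_ids[i], sym[i, ]), collapse = "\t"), character(1))
  c(header, body)
}

#' Write / parse the lollipop TSV
#'
#' @param m A [methylation_call_matrix()].
#' @param path File path.
#' @return `write_lollipop` returns the path invisibly; `read_lollipop`
#'   returns the [methylation_call_matrix()] reconstructed from the file
#'   (reads in file order).
#' @export
write_lollipop <- function(m, path) {
  writeLines(render_lollipop(m), path)
  invisible(path)
}

#' @rdname write_lollipop
#' @param lines Parsed instead of `path` when supplied.
#' @export
read_lollipop <- function(path, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sites <- as.numeric(header[-1])
  if (length(lines) == 1)
    return(methylation_call_matrix(matrix(NA_real_, 0, length(sites)),
                                   cpg_sites = sites,
                                   read_ids = character(0)))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  sym <- do.call(rbind, lapply(parts, `[`, -1))
  calls <- matrix(NA_real_, nrow(sym), ncol(sym))
  calls[sym == LOLLIPOP_SYMBOLS["methylated"]] <- 1
  calls[sym == LOLLIPOP_SYMBOLS["unmethylated"]] <- 0
  methylation_call_matrix(calls, cpg_sites = sites, read_ids = ids)
}
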