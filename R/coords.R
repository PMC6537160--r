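#' Parse a whole-genome alignment block table
#'
#' Reads the tab dialect produced by `show-coords -T -H` (MUMmer):
#' columns S1 E1 S2 E2 LEN1 LEN2 %IDY TAG1 TAG2, no header.  A descending
#' query interval (S2 > E2) marks an inverted block; the interval is
#' normalised ascending and the orientation recorded.
#'
#' @param path path to the coords file.
#' @return data.frame with columns `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end`, `identity`, `orientation`
#'   ("forward" or "inverted").
#' @export
parse_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty coords file: ", path)
    return(data.frame(ref_chrom = character(0), ref_start = integer(0),
                      ref_end = integer(0), qry_chrom = character(0),
                      qry_start = integer(0), qry_end = integer(0),
                      identity = numeric(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(f) != 9) {
      stop(sprintf("malformed coords row at line %d: expected 9 fields, got %d",
                   i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[1:7]))
    if (any(is.na(num))) {
      stop(sprintf("malformed coords row at line %d: non-numeric field", i))
    }
    s1 <- num[1]; e1 <- num[2]; s2 <- num[3]; e2 <- num[4]
    inverted <- s2 > e2
    out[[i]] <- data.frame(
      ref_chrom = f[8], ref_start = as.integer(min(s1, e1)),
      ref_end = as.integer(max(s1, e1)), qry_chrom = f[9],
      qry_start = as.integer(min(s2, e2)), qry_end = as.integer(max(s2, e2)),
      identity = num[7],
      orientation = if (inverted) "inverted" else "forward",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a block table in the show-coords tab dialect
#'
#' @param blocks a block data.frame as returned by [parse_coords()] (the
#'   `orientation` column controls whether the query interval is written
#'   descending).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_coords <- function(blocks, path) {
  if (is.null(blocks) || !nrow(blocks)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  inv <- blocks$orientation == "inverted"
  s2 <- ifelse(inv, blocks$qry_end, blocks$qry_start)
  e2 <- ifelse(inv, blocks$qry_start, blocks$qry_end)
  lines <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                   blocks$ref_start, blocks$ref_end, s2, e2,
                   blocks$ref_end - blocks$ref_start + 1L,
                   abs(blocks$qry_end - blocks$qry_start) + 1L,
                   blocks$identity, blocks$ref_chrom, blocks$qry_chrom)
  writeLines(lines, path)
  invisible(path)
}
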