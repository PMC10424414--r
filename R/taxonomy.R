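#' Canonical taxonomic ranks
#'
#' The seven greengenes-style ranks used throughout the package, in order from
#' kingdom to species, together with their conventional string prefixes
#' (`k__`, `p__`, ..., `s__`).
#'
#' @return Named character vector of rank prefixes, names are rank names.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
    family = "f__", genus = "g__", species = "s__")
}

.rank_index <- function(level) {
  ranks <- names(tax_ranks())
  i <- match(level, ranks)
  if (is.na(i)) stop("unknown taxonomic rank: ", level, call. = FALSE)
  i
}

#' Parse taxonomy strings into a rank matrix
#'
#' Splits semicolon-delimited taxonomy strings into a character matrix with one
#' column per canonical rank. Labels carrying greengenes-style prefixes
#' (`k__Bacteria`) are placed by prefix; unprefixed labels are assigned ranks
#' positionally. Missing ranks are `NA`.
#'
#' @param x Character vector of taxonomy strings.
#' @return Character matrix, `length(x)` rows by 7 rank columns (bare labels,
#'   prefixes stripped), with `x` as rownames-free attribute-less payload.
#' @export
#' @examples
#' parse_taxonomy("k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales")
parse_taxonomy <- function(x) {
  stopifnot(is.character(x))
  ranks <- names(tax_ranks())
  prefixes <- unname(tax_ranks())
  out <- matrix(NA_character_, nrow = length(x), ncol = length(ranks),
                dimnames = list(NULL, ranks))
  bad <- character(0)
  for (i in seq_along(x)) {
    tokens <- trimws(strsplit(x[[i]], ";", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) {
      bad <- c(bad, x[[i]])
      next
    }
    last_rank <- 0L
    ok <- TRUE
    for (tok in tokens) {
      hit <- which(startsWith(tok, prefixes))
      if (length(hit) == 1L) {
        r <- hit
        label <- substring(tok, nchar(prefixes[r]) + 1L)
      } else {
        r <- last_rank + 1L
        label <- tok
      }
      if (r <= last_rank || r > length(ranks)) {
        ok <- FALSE
        break
      }
      out[i, r] <- if (nzchar(label)) label else NA_character_
      last_rank <- r
    }
    if (!ok) bad <- c(bad, x[[i]])
  }
  if (length(bad)) {
    stop("unparseable taxonomy label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Serialize a rank matrix back to taxonomy strings
#'
#' Inverse of [parse_taxonomy()] for canonical strings: ranks are emitted in
#' order with their prefixes, trailing missing ranks are dropped.
#'
#' @param mat Character matrix as returned by [parse_taxonomy()].
#' @return Character vector of taxonomy strings.
#' @export
format_taxonomy <- function(mat) {
  prefixes <- unname(tax_ranks())
  apply(mat, 1L, function(row) {
    keep <- which(!is.na(row))
    if (!length(keep)) return("")
    upto <- max(keep)
    row <- row[seq_len(upto)]
    row[is.na(row)] <- ""
    paste0(prefixes[seq_len(upto)], row, collapse = ";")
  })
}

#' Complete taxonomy paths to a fixed depth
#'
#' Fills missing intermediate and trailing ranks with
#' `"<parent-label>__unclassified"` placeholders so that every path runs
#' root-to-leaf at the requested depth. The taxonomy-image builder requires
#' complete paths.
#'
#' @param x Character vector of taxonomy strings.
#' @param depth Rank name the paths should reach (default `"species"`).
#' @return Character vector of completed taxonomy strings.
#' @export
#' @examples
#' complete_taxonomy("k__Bacteria;p__Firmicutes", depth = "order")
complete_taxonomy <- function(x, depth = "species") {
  d <- .rank_index(depth)
  mat <- parse_taxonomy(x)
  for (i in seq_len(nrow(mat))) {
    parent <- if (!is.na(mat[i, 1L])) mat[i, 1L] else "root"
    for (r in seq_len(d)) {
      if (is.na(mat[i, r])) {
        mat[i, r] <- paste0(parent, "__unclassified")
      }
      parent <- mat[i, r]
    }
    if (d < ncol(mat)) mat[i, (d + 1L):ncol(mat)] <- NA_character_
  }
  format_taxonomy(mat)
}
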