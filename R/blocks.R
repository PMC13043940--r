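#' Phase heterozygous sites of one block
#'
#' Distribute a block's heterozygous sites onto the two sampled haplotypes by
#' binomial phasing: each of the `h` heterozygous sites lands on the sampled
#' haplotype with probability 1/2, so the block contributes weight
#' `dbinom(j, h, 1/2)` to the difference class `S = d + j`. A block with two
#' fixed differences and one heterozygous site contributes 1/2 each to
#' `S = 2` and `S = 3`.
#'
#' @param d Count of fixed inter-specific differences (non-negative integer).
#' @param h Count of heterozygous sites in the block (non-negative integer).
#' @return A tibble with columns `S` (`d .. d + h`) and `weight`
#'   (summing to 1).
#' @examples
#' phase_block(2, 1)
#' phase_block(2, 2)
#' @export
phase_block <- function(d, h) {
  if (length(d) != 1L || length(h) != 1L || is.na(d) || is.na(h) ||
      d < 0 || h < 0 || d != round(d) || h != round(h)) {
    stop("d and h must be single non-negative integers", call. = FALSE)
  }
  j <- 0:h
  # choose()/2^h is exact in binary floating point for the h seen in blocks
  tibble::tibble(S = as.integer(d + j), weight = choose(h, j) / 2^h)
}

new_sdist <- function(counts, n_blocks, norm_total = NULL, pair_id = NA_character_) {
  out <- tibble::tibble(k = seq_along(counts) - 1L, count = counts)
  class(out) <- c("sdist", class(out))
  attr(out, "n_blocks") <- n_blocks
  attr(out, "norm_total") <- norm_total
  attr(out, "pair_id") <- pair_id
  out
}

#' Build the S-distribution of a species pair
#'
#' Sum the binomially phased weight vectors of all blocks into a (possibly
#' fractional) histogram of pairwise differences `S`, optionally rescaled so
#' the total weight equals `normalize_total` (the cross-pair normalisation
#' `500 / n_i` that makes log-likelihood differences comparable between pairs
#' with different block counts).
#'
#' @param blocks A data frame of block records with integer columns `d`
#'   (fixed differences) and `h` (heterozygous sites); typically from
#'   [read_block_table()] or [simulate_blocks()].
#' @param normalize_total Target total weight after normalisation (the
#'   conventional default is 500), or `NULL` to keep the raw per-block total.
#' @param pair_id Optional pair identifier carried into outputs.
#' @return A tibble of class `sdist` with columns `k` and `count`, and
#'   attributes `n_blocks`, `norm_total` and `pair_id`. Before normalisation
#'   the counts sum to the number of blocks.
#' @examples
#' blocks <- tibble::tibble(block_id = c("b1", "b2"), length = c(100L, 100L),
#'                          d = c(2L, 2L), h = c(1L, 1L))
#' build_sdist(blocks, normalize_total = NULL)
#' @export
build_sdist <- function(blocks, normalize_total = 500, pair_id = NA_character_) {
  validate_blocks(blocks)
  d <- as.integer(blocks$d)
  h <- as.integer(blocks$h)
  kmax <- max(d + h)
  counts <- numeric(kmax + 1L)
  # aggregate identical (d, h) pairs: one phasing vector each
  key <- paste(d, h)
  for (grp in split(seq_along(key), key)) {
    w <- phase_block(d[grp[1]], h[grp[1]])
    counts[w$S + 1L] <- counts[w$S + 1L] + length(grp) * w$weight
  }
  n_blocks <- nrow(blocks)
  if (!is.null(normalize_total)) {
    counts <- counts * normalize_total / n_blocks
  }
  new_sdist(counts, n_blocks, normalize_total, pair_id)
}

validate_blocks <- function(blocks) {
  if (!is.data.frame(blocks) || nrow(blocks) == 0) {
    stop("`blocks` must be a non-empty data frame of block records", call. = FALSE)
  }
  need <- c("d", "h")
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    stop("block table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_int <- function(x) is.na(x) | x < 0 | x != round(x)
  bad <- bad_int(blocks$d) | bad_int(blocks$h)
  if (!is.null(blocks$length)) {
    bad <- bad | bad_int(blocks$length) | (blocks$d + blocks$h > blocks$length)
  }
  if (any(bad)) {
    id <- if (!is.null(blocks$block_id)) blocks$block_id[which(bad)[1]] else which(bad)[1]
    stop(sprintf("invalid block record (block %s): d, h must be non-negative integers with d + h <= length",
                 id), call. = FALSE)
  }
  invisible(blocks)
}

#' Read and write block tables
#'
#' Block tables are UTF-8, LF-terminated, tab-separated files with a header
#' naming `block_id`, `length`, `d` (fixed inter-specific differences) and
#' `h` (heterozygous sites).
#'
#' @param path File path.
#' @return `read_block_table()` returns a tibble of validated block records;
#'   `write_block_table()` returns `path` invisibly.
#' @export
read_block_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("block_id", "length", "d", "h")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("block table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("length", "d", "h")) {
    x <- tab[[col]]
    bad <- is.na(suppressWarnings(as.numeric(x))) | as.numeric(x) != round(as.numeric(x))
    if (any(bad)) {
      stop(sprintf("%s: non-integer value in column '%s' at line %d",
                   path, col, which(bad)[1] + 1L), call. = FALSE)
    }
    tab[[col]] <- as.integer(x)
  }
  bad <- tab$d < 0 | tab$h < 0 | tab$d + tab$h > tab$length
  if (any(bad)) {
    stop(sprintf("%s: invalid block record at line %d (need d >= 0, h >= 0, d + h <= length)",
                 path, which(bad)[1] + 1L), call. = FALSE)
  }
  tibble::as_tibble(tab[need])
}

#' @param blocks A block-record data frame (columns `block_id`, `length`,
#'   `d`, `h`).
#' @rdname read_block_table
#' @export
write_block_table <- function(blocks, path) {
  validate_blocks(blocks)
  readr::write_tsv(blocks[c("block_id", "length", "d", "h")], path)
  invisible(path)
}

#' Write an S-distribution to TSV
#'
#' @param sdist An `sdist` object from [build_sdist()].
#' @param path File path; written as a two-column TSV `k  count`.
#' @return `path`, invisibly.
#' @export
write_sdist <- function(sdist, path) {
  stopifnot(inherits(sdist, "sdist"))
  readr::write_tsv(tibble::tibble(k = sdist$k, count = sdist$count), path)
  invisible(path)
}

#' @export
print.sdist <- function(x, ...) {
  cat(sprintf("<sdist> %d blocks, total weight %.6g%s\n",
              attr(x, "n_blocks"), sum(x$count),
              if (is.null(attr(x, "norm_total"))) "" else
                sprintf(" (normalised to %g)", attr(x, "norm_total"))))
  NextMethod()
}
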