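.conditions <- c("tenderness", "pride", "neutral")
.emotional <- c("tenderness", "pride")

#' Construct a validated block design
#'
#' A block design is an ordered sequence of condition blocks making up one
#' acquisition run.  Every emotional (tenderness or pride) block must be
#' immediately preceded by a neutral block, because the decoder normalises
#' each emotional volume against the mean of the preceding neutral block.
#'
#' @param blocks data frame with columns `condition` (one of `"tenderness"`,
#'   `"pride"`, `"neutral"`) and `n_volumes` (positive integer counts).
#' @param run_id integer run identifier (0-based).
#' @param tr_seconds repetition time in seconds (volume-to-volume interval).
#' @param start_condition which emotional condition occurs first; inferred
#'   from `blocks` when `NULL`.
#' @return An object of class `block_design`: a list with elements `blocks`,
#'   `run_id`, `tr_seconds`, `start_condition` and `n_volumes` (the total).
#' @seealso [make_default_design()], [label_volumes()]
#' @export
block_design <- function(blocks, run_id = 0L, tr_seconds = 2,
                         start_condition = NULL) {
  stopifnot(is.data.frame(blocks), all(c("condition", "n_volumes") %in%
                                         names(blocks)))
  blocks <- data.frame(condition = as.character(blocks$condition),
                       n_volumes = as.integer(blocks$n_volumes))
  if (!all(blocks$condition %in% .conditions))
    stop("invalid design: unknown condition in block list")
  if (any(blocks$n_volumes <= 0L))
    stop("invalid design: every block needs n_volumes > 0")
  emo <- blocks$condition %in% .emotional
  if (any(emo & blocks$n_volumes <= 2L))
    stop("invalid design: emotional blocks need n_volumes > 2 (first two ",
         "volumes of each block are excluded from decoding)")
  # every emotional block must directly follow a neutral block
  prev <- c(NA_character_, blocks$condition[-nrow(blocks)])
  if (any(emo & (is.na(prev) | prev != "neutral")))
    stop("invalid design: every emotional block must be immediately ",
         "preceded by a neutral block")
  if (is.null(start_condition)) {
    first_emo <- blocks$condition[emo]
    start_condition <- if (length(first_emo)) first_emo[1L] else NA_character_
  }
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(list(blocks = blocks,
                 run_id = as.integer(run_id),
                 tr_seconds = tr_seconds,
                 start_condition = start_condition,
                 n_volumes = sum(blocks$n_volumes)),
            class = "block_design")
}

#' Default alternating run protocol
#'
#' Builds the standard run used throughout: 8 neutral blocks of 15 volumes
#' interleaved with 8 emotional blocks of 22 volumes (4 tenderness, 4 pride,
#' strictly alternating), i.e. 296 volumes at TR = 2 s, about 10 minutes.
#' The emotional sequence begins with `start_condition`; counterbalancing
#' across subjects or groups is the caller's responsibility.
#'
#' @param start_condition `"tenderness"` or `"pride"`; the first emotional
#'   block's condition.
#' @param run_id integer run identifier (0-based).
#' @return A [block_design()] with 16 blocks and 296 volumes.
#' @examples
#' d <- make_default_design("tenderness")
#' d$n_volumes            # 296
#' table(d$blocks$condition)
#' @export
make_default_design <- function(start_condition = c("tenderness", "pride"),
                                run_id = 0L) {
  start_condition <- match.arg(start_condition)
  other <- setdiff(.emotional, start_condition)
  emo <- rep(c(start_condition, other), 4L)
  cond <- as.vector(rbind("neutral", emo))
  nvol <- ifelse(cond == "neutral", 15L, 22L)
  block_design(data.frame(condition = cond, n_volumes = nvol),
               run_id = run_id, tr_seconds = 2,
               start_condition = start_condition)
}

#' Per-volume condition labels and decoding usability
#'
#' Expands a block design into one row per volume.  A volume is usable for
#' decoder training/classification only if it belongs to an emotional block
#' and is not one of the first two volumes of that block (excluded while the
#' haemodynamic response stabilises).  Neutral volumes are never usable;
#' they serve as the normalisation baseline.
#'
#' @param design a [block_design()].
#' @return data frame with columns `volume_index` (0-based), `condition`,
#'   `block_index` (0-based) and `usable` (logical).
#' @examples
#' lab <- label_volumes(make_default_design())
#' sum(lab$usable & lab$condition == "tenderness")  # 80
#' @export
label_volumes <- function(design) {
  stopifnot(inherits(design, "block_design"))
  b <- design$blocks
  cond <- rep(b$condition, b$n_volumes)
  bidx <- rep(seq_len(nrow(b)) - 1L, b$n_volumes)
  within <- unlist(lapply(b$n_volumes, seq_len)) - 1L
  usable <- cond %in% .emotional & within >= 2L
  data.frame(volume_index = seq_along(cond) - 1L,
             condition = cond,
             block_index = bidx,
             usable = usable)
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> run %d: %d blocks, %d volumes, TR %.1f s\n",
              x$run_id, nrow(x$blocks), x$n_volumes, x$tr_seconds))
  tab <- table(x$blocks$condition)
  cat("  blocks:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a block design as TSV
#'
#' @param design a [block_design()].
#' @param path output file path.
#' @return `write_design_tsv` returns `path` invisibly; `read_design_tsv`
#'   returns a [block_design()].
#' @export
write_design_tsv <- function(design, path) {
  b <- design$blocks
  out <- data.frame(block_index = seq_len(nrow(b)) - 1L,
                    condition = b$condition, n_volumes = b$n_volumes)
  attr_line <- sprintf("# run_id=%d tr_seconds=%g start_condition=%s",
                       design$run_id, design$tr_seconds,
                       design$start_condition)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- list(run_id = 0L, tr_seconds = 2, start_condition = NULL)
  if (startsWith(hdr, "#")) {
    kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1L]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1L]]
      if (length(p) == 2L) meta[[p[1L]]] <- p[2L]
    }
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  block_design(tab[, c("condition", "n_volumes")],
               run_id = as.integer(meta$run_id),
               tr_seconds = as.numeric(meta$tr_seconds),
               start_condition = if (is.null(meta$start_condition)) NULL
                                 else as.character(meta$start_condition))
}

#' Write the expanded per-volume label table as TSV
#'
#' @param labels output of [label_volumes()].
#' @param path output file path.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
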