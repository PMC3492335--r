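#' @name io_formats
#' @title Tab-separated on-disk formats
#'
#' @description
#' Every artifact travels as UTF-8 TSV with optional `#` comment lines.
#' Coordinates are 0-based half-open everywhere. Readers validate strictly
#' and raise classed conditions (`triomics_validation_error` plus a
#' specific subclass) naming the file and offending row rather than
#' silently coercing; only autosomes 1-22 are admitted (sex chromosomes
#' are rejected, not filtered, so input errors stay visible).
#'
#' Formats:
#' * annotation: `chrom start end gene_id arm`
#' * segments:   `sample chrom start end value`
#' * matrix:     first column `probe_id`, one column per sample; role and
#'   control columns recorded as `#role:` / `#controls:` comment lines
#' * calls:      `gene_id sample channel value`, only value-1 rows stored;
#'   `#genes:` / `#samples:` comments carry the full universe so the
#'   round trip is exact
NULL

read_tsv_strict <- function(path, col_names, col_classes) {
  if (!file.exists(path))
    abort_validation("triomics_io_error", sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          colClasses = col_classes, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df), col_names))
    abort_validation("triomics_format_error",
      sprintf("%s: expected columns %s, found %s", path,
              paste(col_names, collapse = ","), paste(names(df), collapse = ",")))
  df
}

comment_lines <- function(path) {
  head_lines <- readLines(path, n = 50L)
  head_lines[startsWith(head_lines, "#")]
}

check_autosomes <- function(chrom, path) {
  bad <- setdiff(unique(chrom), autosomes())
  if (length(bad))
    abort_validation("triomics_chromosome_error",
      sprintf("%s: non-autosomal chromosome(s) %s; only 1-22 are admitted",
              path, paste(bad, collapse = ",")))
}

#' Read / write a gene annotation
#'
#' @param path TSV file.
#' @param annotation a `gene_annotation` data.frame (extra attributes such
#'   as the density field are serialized to `#` comment JSON lines and
#'   restored on read).
#' @return `read_annotation`: a `gene_annotation`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "start", "end", "gene_id", "arm"),
                        c("character", "numeric", "numeric", "character",
                          "character"))
  check_autosomes(df$chrom, path)
  if (anyDuplicated(df$gene_id))
    abort_validation("triomics_duplicate_error",
      sprintf("%s: duplicate gene_id '%s'", path,
              df$gene_id[anyDuplicated(df$gene_id)]))
  bad <- which(df$end <= df$start)
  if (length(bad))
    abort_validation("triomics_interval_error",
      sprintf("%s: row %d (gene %s): end <= start", path, bad[1],
              df$gene_id[bad[1]]))
  if (!all(df$arm %in% c("p", "q")))
    abort_validation("triomics_format_error",
                     sprintf("%s: arm must be 'p' or 'q'", path))
  meta <- comment_lines(path)
  ann <- structure(df, class = c("gene_annotation", "data.frame"))
  mjson <- sub("^#meta:", "", meta[startsWith(meta, "#meta:")])
  if (length(mjson) == 1L) {
    m <- jsonlite::fromJSON(mjson)
    attr(ann, "chrom_lengths") <- unlist(m$chrom_lengths)
    attr(ann, "centromeres") <- unlist(m$centromeres)
    if (!is.null(m$density)) attr(ann, "density") <- as.data.frame(m$density)
  }
  ann
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- list(chrom_lengths = as.list(attr(annotation, "chrom_lengths")),
               centromeres = as.list(attr(annotation, "centromeres")),
               density = attr(annotation, "density"))
  if (!is.null(meta$chrom_lengths))
    writeLines(paste0("#meta:", jsonlite::toJSON(meta, digits = NA,
                                                 auto_unbox = TRUE)), con)
  utils::write.table(as.data.frame(annotation)[, c("chrom", "start", "end",
                                                   "gene_id", "arm")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_segments <- function(df, path = "<segments>") {
  check_autosomes(df$chrom, path)
  if (any(!is.finite(df$value)))
    abort_validation("triomics_value_error",
      sprintf("%s: non-finite segment value at row %d", path,
              which(!is.finite(df$value))[1]))
  if (any(df$end <= df$start))
    abort_validation("triomics_interval_error",
      sprintf("%s: segment with end <= start at row %d", path,
              which(df$end <= df$start)[1]))
  key <- if ("sample" %in% names(df)) paste(df$sample, df$chrom) else df$chrom
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    o <- order(sub$start)
    if (any(sub$start[o][-1] < sub$end[o][-nrow(sub)]))
      abort_validation("triomics_overlap_error",
        sprintf("%s: overlapping segments on '%s'", path, k))
  }
  invisible(df)
}

#' Read / write segmented copy-number tracks
#'
#' @param path TSV with columns `sample chrom start end value`.
#' @param segments a segments data.frame (the `sample` column may be absent
#'   for a single cohort-level track).
#' @return `read_segments`: the validated data.frame (sorted by sample,
#'   chrom, start).
#' @export
read_segments <- function(path) {
  df <- read_tsv_strict(path, c("sample", "chrom", "start", "end", "value"),
                        c("character", "character", "numeric", "numeric",
                          "numeric"))
  validate_segments(df, path)
  df[order(df$sample, match(df$chrom, autosomes()), df$start), ]
}

#' @rdname read_segments
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  if (!"sample" %in% names(segments))
    segments <- cbind(sample = ".", segments)
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a probe-by-sample omics matrix
#'
#' @param path TSV; first column `probe_id`, remaining columns samples.
#' @param role one of `beta`, `mvalue`, `vst`, `logratio`; defaults to the
#'   `#role:` comment in the file.
#' @param x numeric matrix with `role` and `controls` attributes.
#' @return `read_matrix`: a numeric matrix with `role` / `controls`
#'   attributes; beta-role values are checked to lie in `[0,1]`.
#' @export
read_matrix <- function(path, role = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    abort_validation("triomics_format_error",
                     sprintf("%s: first column must be probe_id", path))
  if (anyDuplicated(df$probe_id))
    abort_validation("triomics_duplicate_error",
      sprintf("%s: duplicate probe_id '%s'", path,
              df$probe_id[anyDuplicated(df$probe_id)]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    abort_validation("triomics_value_error",
                     sprintf("%s: non-numeric matrix entries", path))
  rownames(m) <- df$probe_id
  meta <- comment_lines(path)
  role_line <- sub("^#role:\\s*", "", meta[startsWith(meta, "#role:")])
  ctrl_line <- sub("^#controls:\\s*", "", meta[startsWith(meta, "#controls:")])
  role <- role %||% (if (length(role_line)) role_line else
    abort_validation("triomics_format_error",
                     sprintf("%s: no role given and no #role: comment", path)))
  if (!role %in% c("beta", "mvalue", "vst", "logratio"))
    abort_validation("triomics_format_error",
                     sprintf("%s: unknown role '%s'", path, role))
  if (role == "beta") {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad))
      abort_validation("triomics_value_error",
        sprintf("%s: beta value %.3g out of [0,1] at probe '%s', sample '%s'",
                path, m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                colnames(m)[bad[1, 2]]))
  }
  attr(m, "role") <- role
  if (length(ctrl_line)) {
    ctrls <- strsplit(ctrl_line, ",", fixed = TRUE)[[1]]
    missing <- setdiff(ctrls, colnames(m))
    if (length(missing))
      abort_validation("triomics_control_error",
        sprintf("%s: control column(s) %s absent", path,
                paste(missing, collapse = ",")))
    attr(m, "controls") <- ctrls
  }
  m
}

#' @rdname read_matrix
#' @export
write_matrix <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(attr(x, "role")))
    writeLines(paste0("#role: ", attr(x, "role")), con)
  if (!is.null(attr(x, "controls")))
    writeLines(paste0("#controls: ", paste(attr(x, "controls"),
                                           collapse = ",")), con)
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe-to-gene map
#' @param path two-column TSV `probe_id gene_id`.
#' @param map a data.frame with those columns.
#' @export
read_probe_map <- function(path) {
  read_tsv_strict(path, c("probe_id", "gene_id"), c("character", "character"))
}

#' @rdname read_probe_map
#' @export
write_probe_map <- function(map, path) {
  utils::write.table(map[, c("probe_id", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a call matrix
#'
#' One file holds all six aberration channels in long form (gene, sample,
#' channel, value); a compatibility writer, [write_calls_per_channel()],
#' emits the six-file one-channel-per-file layout instead.
#'
#' @param calls a [call_matrix()].
#' @param path TSV file.
#' @return `read_calls`: a `call_matrix`.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "call_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#genes: ", paste(calls$genes, collapse = ",")),
               paste0("#samples: ", paste(calls$samples, collapse = ","))), con)
  rows <- lapply(call_channels(), function(ch) {
    hit <- which(calls$channels[[ch]], arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(gene_id = calls$genes[hit[, 1]],
               sample = calls$samples[hit[, 2]],
               channel = ch, value = 1L)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(gene_id = character(0), sample = character(0),
                     channel = character(0), value = integer(0))
  df <- df[order(df$gene_id, df$sample, df$channel), ]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_tsv_strict(path, c("gene_id", "sample", "channel", "value"),
                        c("character", "character", "character", "integer"))
  meta <- comment_lines(path)
  genes <- strsplit(sub("^#genes: ", "", meta[startsWith(meta, "#genes:")]),
                    ",", fixed = TRUE)[[1]]
  samples <- strsplit(sub("^#samples: ", "",
                          meta[startsWith(meta, "#samples:")]),
                      ",", fixed = TRUE)[[1]]
  if (!all(df$channel %in% call_channels()))
    abort_validation("triomics_format_error",
      sprintf("%s: unknown channel '%s'", path,
              setdiff(df$channel, call_channels())[1]))
  if (!all(df$value == 1L))
    abort_validation("triomics_value_error",
      sprintf("%s: stored call values must all be 1", path))
  if (!all(df$gene_id %in% genes) || !all(df$sample %in% samples))
    abort_validation("triomics_format_error",
      sprintf("%s: call row outside the declared gene/sample universe", path))
  ch <- lapply(call_channels(), function(cc) {
    m <- matrix(FALSE, length(genes), length(samples),
                dimnames = list(genes, samples))
    sub <- df[df$channel == cc, , drop = FALSE]
    m[cbind(match(sub$gene_id, genes), match(sub$sample, samples))] <- TRUE
    m
  })
  names(ch) <- call_channels()
  call_matrix(genes, samples, ch)
}

#' @rdname write_calls
#' @param dir output directory for the six per-channel files
#'   (`calls_<channel>.tsv`, genes x samples 0/1 tables).
#' @export
write_calls_per_channel <- function(calls, dir) {
  stopifnot(inherits(calls, "call_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in call_channels()) {
    df <- data.frame(gene_id = calls$genes,
                     calls$channels[[ch]] + 0L, check.names = FALSE)
    utils::write.table(df, file.path(dir, sprintf("calls_%s.tsv", ch)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
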