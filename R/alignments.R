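#' Read alignment records from a BAM file into a tibble
#'
#' Loads one record per aligned read with the fields the caller consumes:
#' position, mapping quality, CIGAR, flag booleans, mate information,
#' template length, and the `SA` (supplementary) / `XA` (alternative
#' alignment) tags. Coordinates are converted to the 0-based half-open
#' convention used everywhere inside the package; they are shifted back to
#' 1-based only by the VCF writer.
#'
#' @param bam_path path to a coordinate-sorted BAM file.
#' @param region optional region as a `GenomicRanges::GRanges` or a
#'   `"chrom:start-end"` string (1-based, as accepted by samtools); requires
#'   a BAM index.
#' @param with_seq logical; load read sequences (needed for consensus
#'   building, skippable for the genome-wide first pass).
#' @param with_qname logical; load query names.
#' @param with_tags logical; load the SA/XA tag strings (skippable for
#'   passes that only need positions and flags).
#' @param sample_id override the sample label; by default the `SM` field of
#'   the first `@RG` header line, falling back to the file basename.
#' @return a tibble with one row per BAM record: `qname` (if requested),
#'   `sample_id`, `chrom`, `pos` (0-based leftmost), `mapq`, `cigar`,
#'   flag booleans (`paired`, `proper_pair`, `reverse`, `mate_reverse`,
#'   `secondary`, `supplementary`, `duplicate`, `unmapped`,
#'   `mate_unmapped`), `seq` (or `NA`), `mate_chrom`, `mate_pos`, `tlen`,
#'   `sa`, `xa` (raw tag strings, `NA` when absent), plus derived CIGAR
#'   columns from [add_cigar_info()].
#' @export
read_alignments <- function(bam_path, region = NULL, with_seq = TRUE,
                            with_qname = FALSE, with_tags = TRUE,
                            sample_id = NULL) {
  if (!file.exists(bam_path)) {
    stop("BAM file not found: ", bam_path, call. = FALSE)
  }
  hdr <- tryCatch(Rsamtools::scanBamHeader(bam_path)[[1]],
                  error = function(e) {
                    stop("cannot read BAM header of ", bam_path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  so <- grep("^SO:", unlist(hdr$text[names(hdr$text) == "@HD"]), value = TRUE)
  if (length(so) && !so[1] %in% c("SO:coordinate", "SO:unknown")) {
    stop("BAM file is not coordinate-sorted: ", bam_path, call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- header_sample_id(hdr, bam_path)

  which <- NULL
  if (!is.null(region)) {
    if (is.na(bam_index_path(bam_path))) {
      stop("region query requires a BAM index (.bai) for ", bam_path,
           call. = FALSE)
    }
    which <- as_region_granges(region)
  }

  what <- c("flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos", "isize")
  if (with_seq) what <- c(what, "seq")
  if (with_qname) what <- c("qname", what)
  param_args <- list(what = what)
  if (with_tags) param_args$tag <- c("SA", "XA")
  if (!is.null(which)) param_args$which <- which
  param <- do.call(Rsamtools::ScanBamParam, param_args)

  chunks <- Rsamtools::scanBam(bam_path, param = param)
  res <- purrr::map(chunks, scan_chunk_to_tibble, sample_id = sample_id,
                    with_seq = with_seq, with_qname = with_qname)
  out <- dplyr::bind_rows(res)
  add_cigar_info(out)
}

header_sample_id <- function(hdr, bam_path) {
  rg <- unlist(hdr$text[names(hdr$text) == "@RG"])
  sm <- grep("^SM:", rg, value = TRUE)
  if (length(sm)) unname(sub("^SM:", "", sm[1])) else
    sub("\\.bam$", "", basename(bam_path))
}

bam_index_path <- function(bam_path) {
  cands <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  cands[file.exists(cands)][1]
}

as_region_granges <- function(region) {
  if (inherits(region, "GRanges")) return(region)
  m <- stringr::str_match(region, "^([^:]+):(\\d+)-(\\d+)$")
  if (is.na(m[1, 1])) stop("malformed region string: ", region, call. = FALSE)
  GenomicRanges::GRanges(m[1, 2],
                         IRanges::IRanges(as.integer(m[1, 3]),
                                          as.integer(m[1, 4])))
}

scan_chunk_to_tibble <- function(x, sample_id, with_seq, with_qname) {
  n <- length(x$flag)
  fl <- x$flag
  out <- tibble::tibble(
    sample_id     = rep(sample_id, n),
    chrom         = as.character(x$rname),
    pos           = as.integer(x$pos) - 1L,
    mapq          = as.integer(x$mapq),
    cigar         = as.character(x$cigar),
    paired        = bitwAnd(fl, 1L) > 0L,
    proper_pair   = bitwAnd(fl, 2L) > 0L,
    unmapped      = bitwAnd(fl, 4L) > 0L,
    mate_unmapped = bitwAnd(fl, 8L) > 0L,
    reverse       = bitwAnd(fl, 16L) > 0L,
    mate_reverse  = bitwAnd(fl, 32L) > 0L,
    secondary     = bitwAnd(fl, 256L) > 0L,
    duplicate     = bitwAnd(fl, 1024L) > 0L,
    supplementary = bitwAnd(fl, 2048L) > 0L,
    mate_chrom    = as.character(x$mrnm),
    mate_pos      = as.integer(x$mpos) - 1L,
    tlen          = as.integer(x$isize),
    sa            = x$tag$SA %||% rep(NA_character_, n),
    xa            = x$tag$XA %||% rep(NA_character_, n)
  )
  if (with_qname) out <- tibble::add_column(out, qname = x$qname, .before = 1)
  out$seq <- if (with_seq) as.character(x$seq) else rep(NA_character_, n)
  out
}

#' Add derived CIGAR columns to a reads tibble
#'
#' Computes, per record: `ref_span` (reference bases consumed), and the
#' length/operator of any leading and trailing clip (`clip_left_len`,
#' `clip_left_op`, `clip_right_len`, `clip_right_op`; length 0 when the read
#' is not clipped on that side). The computation runs over unique CIGAR
#' strings only, which keeps genome-scale passes cheap since the vast
#' majority of records share a handful of CIGARs.
#'
#' @param reads a reads tibble with a `cigar` column.
#' @return the tibble with derived columns appended.
#' @export
add_cigar_info <- function(reads) {
  u <- unique(reads$cigar)
  u_ok <- !is.na(u) & u != "*"
  span <- rep(NA_integer_, length(u))
  span[u_ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(u[u_ok])
  lead <- stringr::str_match(u, "^(\\d+)([SH])")
  trail <- stringr::str_match(u, "(\\d+)([SH])$")
  i <- match(reads$cigar, u)
  reads$ref_span <- span[i]
  reads$clip_left_len <- ifelse(is.na(lead[i, 2]), 0L, as.integer(lead[i, 2]))
  reads$clip_left_op <- lead[i, 3]
  reads$clip_right_len <- ifelse(is.na(trail[i, 2]), 0L, as.integer(trail[i, 2]))
  reads$clip_right_op <- trail[i, 3]
  reads
}

#' Parse SA/XA tag strings into per-alignment rows
#'
#' Both bwa tag dialects are understood: the `SA` grammar
#' `"rname,pos,strand,CIGAR,mapQ,NM;"` and the `XA` grammar
#' `"rname,{+,-}pos,CIGAR,NM;"` (strand folded into the position sign).
#' Tag positions are 1-based and converted to the package's 0-based
#' convention here. `XA` entries carry no per-entry mapping quality; the
#' sentinel `-1` is stored and never used in any likelihood.
#'
#' Parsing is total: malformed entries are skipped with a warning and never
#' abort a run.
#'
#' @param tag_value a single tag string (may be `NA` or empty).
#' @return a tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `cigar`, `mapq`, `nm` and `ref_span`; zero rows when the tag is empty.
#' @export
parse_tag_alignments <- function(tag_value) {
  out <- parse_tags_many(tag_value)
  out$tag_idx <- NULL
  out
}

# vectorized over a character vector of tags; `tag_idx` maps rows back to
# the input element they came from
parse_tags_many <- function(tags) {
  empty <- tibble::tibble(tag_idx = integer(), chrom = character(),
                          pos = integer(), strand = character(),
                          cigar = character(), mapq = integer(),
                          nm = integer(), ref_span = integer())
  keep <- which(!is.na(tags) & nzchar(tags))
  if (!length(keep)) return(empty)
  entries <- strsplit(tags[keep], ";", fixed = TRUE)
  n_per <- lengths(entries)
  idx <- rep(keep, n_per)
  flat <- unlist(entries, use.names = FALSE)
  nz <- nzchar(flat)
  idx <- idx[nz]; flat <- flat[nz]
  if (!length(flat)) return(empty)
  fields <- strsplit(flat, ",", fixed = TRUE)
  nf <- lengths(fields)

  parse_block <- function(sel, dialect) {
    if (!any(sel)) return(empty)
    m <- matrix(unlist(fields[sel], use.names = FALSE),
                ncol = if (dialect == "SA") 6L else 4L, byrow = TRUE)
    if (dialect == "SA") {
      tibble::tibble(tag_idx = idx[sel], chrom = m[, 1],
                     pos = suppressWarnings(as.integer(m[, 2])) - 1L,
                     strand = m[, 3], cigar = m[, 4],
                     mapq = suppressWarnings(as.integer(m[, 5])),
                     nm = suppressWarnings(as.integer(m[, 6])))
    } else {
      strand <- ifelse(startsWith(m[, 2], "-"), "-", "+")
      tibble::tibble(tag_idx = idx[sel], chrom = m[, 1],
                     pos = suppressWarnings(
                       as.integer(sub("^[+-]", "", m[, 2]))) - 1L,
                     strand = strand, cigar = m[, 3],
                     mapq = -1L,
                     nm = suppressWarnings(as.integer(m[, 4])))
    }
  }

  out <- dplyr::bind_rows(parse_block(nf == 6L, "SA"),
                          parse_block(nf == 4L, "XA"))
  n_bad <- sum(!nf %in% c(4L, 6L))
  bad_rows <- is.na(out$pos) | out$pos < 0L | is.na(out$chrom) |
    !out$strand %in% c("+", "-") |
    !grepl("^(\\d+[MIDNSHP=X])+$", out$cigar)
  n_bad <- n_bad + sum(bad_rows)
  if (n_bad > 0) {
    warning(n_bad, " malformed SA/XA tag entr",
            if (n_bad == 1) "y" else "ies", " skipped", call. = FALSE)
    out <- out[!bad_rows, , drop = FALSE]
  }
  if (nrow(out)) {
    out$ref_span <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(out$cigar)
  } else {
    out$ref_span <- integer()
  }
  out[order(out$tag_idx), , drop = FALSE]
}

#' Extract clip signatures from aligned reads
#'
#' Every soft (`S`) or hard (`H`) clip at either end of an alignment marks a
#' putative breakpoint: a leading clip at the read's start position
#' (side `"left"`), a trailing clip at start + reference span
#' (side `"right"`). Soft clips contribute the clipped bases
#' (for consensus building); hard clips contribute position only.
#'
#' @param reads a reads tibble from [read_alignments()] (derived CIGAR
#'   columns are added if missing). Unmapped records are ignored.
#' @return a tibble of signatures: `chrom`, `break_pos`, `side`,
#'   `clip_len`, `clip_seq` (empty string for hard clips or absent
#'   sequence), `read_ref` (row index into `reads`), `sample_id`,
#'   `is_primary`, `mapq`, `duplicate`.
#' @export
clip_signatures <- function(reads) {
  if (!"ref_span" %in% names(reads)) reads <- add_cigar_info(reads)
  reads$..row <- seq_len(nrow(reads))
  mapped <- reads[!reads$unmapped & !is.na(reads$cigar) & reads$cigar != "*", ]

  one_side <- function(df, side) {
    len <- if (side == "left") df$clip_left_len else df$clip_right_len
    op <- if (side == "left") df$clip_left_op else df$clip_right_op
    sel <- len > 0L
    df <- df[sel, ]; len <- len[sel]; op <- op[sel]
    bp <- if (side == "left") df$pos else df$pos + df$ref_span
    seq_known <- !is.na(df$seq) & df$seq != "" & op == "S"
    cs <- character(nrow(df))
    if (any(seq_known)) {
      s <- df$seq[seq_known]
      if (side == "left") {
        cs[seq_known] <- substr(s, 1L, len[seq_known])
      } else {
        nlen <- nchar(s)
        cs[seq_known] <- substr(s, nlen - len[seq_known] + 1L, nlen)
      }
    }
    tibble::tibble(chrom = df$chrom, break_pos = as.integer(bp), side = side,
                   clip_len = len, clip_seq = cs, read_ref = df$..row,
                   sample_id = df$sample_id,
                   is_primary = !df$secondary & !df$supplementary,
                   mapq = df$mapq, duplicate = df$duplicate)
  }
  out <- dplyr::bind_rows(one_side(mapped, "left"), one_side(mapped, "right"))
  dplyr::arrange(out, .data$chrom, .data$break_pos, .data$side)
}
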