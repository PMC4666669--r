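vcf_info_header <- function() {
  c('##INFO=<ID=END,Number=1,Type=Integer,Description="1-based position of the partner breakpoint when on the same chromosome">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed distance to the partner breakpoint (0 for inter-chromosomal calls)">',
    '##INFO=<ID=SP,Number=1,Type=Integer,Description="Primary clipped reads supporting the breakpoint">',
    '##INFO=<ID=AT,Number=14,Type=Float,Description="Fourteen depth-normalised pileup attribute fractions">',
    '##INFO=<ID=WC,Number=1,Type=String,Description="Classified SV type">',
    '##INFO=<ID=WP,Number=.,Type=Float,Description="Per-class SV type probabilities, canonical class order">',
    '##INFO=<ID=LRT,Number=1,Type=Float,Description="Binomial likelihood-ratio D statistic between target and background cohorts">',
    '##INFO=<ID=BE,Number=3,Type=String,Description="Partner breakpoint as chrom,1-based pos,support">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10 genotype likelihoods for 0/0,0/1,1/1">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Reads classified as evidence at the breakpoint">',
    '##FORMAT=<ID=SP,Number=1,Type=Integer,Description="Primary clipped reads supporting the breakpoint in this sample">')
}

#' Write SV calls as VCF 4.2
#'
#' One record per breakpoint: internal 0-based positions are converted to
#' the VCF's 1-based `POS` here (and only here). The partner breakpoint is
#' carried in the `BE` INFO pointer (`chrom,pos,support`); `END`/`SVLEN`
#' summarise it for same-chromosome calls. Support (`SP`), the
#' fourteen-attribute vector (`AT`), classification (`WC`/`WP`) and the
#' association statistic (`LRT`, association mode only) round-trip through
#' [read_sv_vcf()] exactly. Per-sample fields are `GT:GL:DP:SP`.
#'
#' @param calls calls tibble (see [sv_call()] for the column contract);
#'   must be free of duplicate `(chrom, pos, side)` keys.
#' @param samples ordered character vector of sample ids for the genotype
#'   columns.
#' @param reference_name label written to the `##reference` header line.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, samples, reference_name, path) {
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  key <- paste(calls$chrom, calls$pos, calls$side %||% "",
               calls$be_chrom, calls$be_pos, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate-keyed VCF records at ",
         calls$chrom[duplicated(key)][1], ":",
         calls$pos[duplicated(key)][1] + 1L, call. = FALSE)
  }
  header <- c("##fileformat=VCFv4.2",
              paste0("##reference=", reference_name),
              "##source=clipsv",
              vcf_info_header(),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "FORMAT_COLS"), collapse = "\t"))
  # assemble the column header properly (FORMAT + sample columns)
  header[length(header)] <-
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")

  lines <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    info <- c(sprintf("SP=%d", x$support))
    if (!is.na(x$be_chrom)) {
      if (x$be_chrom == x$chrom) {
        info <- c(sprintf("END=%d", max(x$be_pos, x$pos) + 1L),
                  sprintf("SVLEN=%d", x$be_pos - x$pos), info)
      } else {
        info <- c("SVLEN=0", info)
      }
      info <- c(info, sprintf("BE=%s,%d,%d", x$be_chrom, x$be_pos + 1L,
                              x$be_support))
    } else {
      info <- c(sprintf("END=%d", x$pos + 1L), "SVLEN=0", info)
    }
    at <- x$at[[1]]
    if (!is.null(at) && !anyNA(at)) {
      info <- c(info, paste0("AT=", paste(fmt_num(as.numeric(at)),
                                          collapse = ",")))
    }
    if (!is.null(x$wc) && !is.na(x$wc)) {
      info <- c(info, paste0("WC=", x$wc))
      wp <- x$wp[[1]]
      if (!is.null(wp) && !anyNA(wp)) {
        info <- c(info, paste0("WP=", paste(fmt_num(as.numeric(wp)),
                                            collapse = ",")))
      }
    }
    if (!is.null(x$lrt) && !is.na(x$lrt)) {
      info <- c(info, paste0("LRT=", fmt_num(x$lrt)))
    }
    g <- x$genotypes[[1]]
    gcols <- vapply(samples, function(s) {
      j <- match(s, g$sample_id)
      if (is.na(j)) return("./.:0,0,0:0:0")
      int_or_dot <- function(v) if (is.na(v)) "." else sprintf("%d", v)
      sprintf("%s:%s:%s:%s", g$gt[j],
              paste(fmt_num(as.numeric(g$gl[[j]])), collapse = ","),
              int_or_dot(g$dp[j]), int_or_dot(g$sp[j]))
    }, character(1))
    id <- if (!is.null(x$side) && !is.na(x$side)) {
      sprintf("%s_%d_%s", x$chrom, x$pos + 1L, x$side)
    } else "."
    paste(c(x$chrom, x$pos + 1L, id, "N", "<SV>", ".", ".",
            paste(info, collapse = ";"), "GT:GL:DP:SP", gcols),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a clipsv VCF back into a calls tibble
#'
#' Inverse of [write_sv_vcf()]; also reads VCFs from other callers well
#' enough for benchmarking (CHROM/POS plus `END` when present).
#'
#' @param path VCF path.
#' @return calls tibble with 0-based `pos`/`be_pos`, `support`, `at`,
#'   `wc`, `wp`, `lrt`, and a `genotypes` list column.
#' @export
read_sv_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  chrom_line <- hdr[startsWith(hdr, "#CHROM")]
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[-(1:9)] else character()

  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          side = character(), support = integer(),
                          be_chrom = character(), be_pos = integer(),
                          be_support = integer(), at = list(),
                          wc = character(), wp = list(), lrt = numeric(),
                          genotypes = list())
  if (!length(body)) return(empty)

  parts <- strsplit(body, "\t", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    info <- strsplit(p[8], ";", fixed = TRUE)[[1]]
    kv <- stringr::str_match(info, "^([^=]+)=?(.*)$")
    vals <- stats::setNames(kv[, 3], kv[, 2])
    be <- if ("BE" %in% names(vals)) {
      strsplit(vals[["BE"]], ",", fixed = TRUE)[[1]]
    } else NULL
    at <- if ("AT" %in% names(vals)) {
      stats::setNames(as.numeric(strsplit(vals[["AT"]], ",")[[1]]),
                      attribute_names())
    } else NULL
    wp <- if ("WP" %in% names(vals)) {
      as.numeric(strsplit(vals[["WP"]], ",")[[1]])
    } else NULL
    gts <- if (length(samples)) {
      fmt <- strsplit(p[9], ":", fixed = TRUE)[[1]]
      g <- lapply(p[-(1:9)], function(s) strsplit(s, ":", fixed = TRUE)[[1]])
      fld <- function(v, key) {
        j <- match(key, fmt)
        if (is.na(j) || j > length(v) || v[j] == ".") NA_character_
        else v[j]
      }
      tibble::tibble(
        sample_id = samples,
        gt = vapply(g, function(v) fld(v, "GT"), character(1)),
        gl = lapply(g, function(v) {
          x <- fld(v, "GL")
          if (is.na(x)) NA_real_ else as.numeric(strsplit(x, ",")[[1]])
        }),
        dp = vapply(g, function(v) {
          x <- fld(v, "DP")
          if (is.na(x)) NA_integer_ else as.integer(x)
        }, integer(1)),
        sp = vapply(g, function(v) {
          x <- fld(v, "SP")
          if (is.na(x)) NA_integer_ else as.integer(x)
        }, integer(1)))
    } else {
      tibble::tibble(sample_id = character(), gt = character(),
                     gl = list(), dp = integer(), sp = integer())
    }
    side <- if (grepl("_(left|right)$", p[3])) {
      sub(".*_", "", p[3])
    } else NA_character_
    tibble::tibble(
      chrom = p[1], pos = as.integer(p[2]) - 1L, side = side,
      support = if ("SP" %in% names(vals))
        as.integer(vals[["SP"]]) else NA_integer_,
      be_chrom = if (!is.null(be)) be[1] else NA_character_,
      be_pos = if (!is.null(be)) as.integer(be[2]) - 1L else
        if ("END" %in% names(vals)) as.integer(vals[["END"]]) - 1L else
          NA_integer_,
      be_support = if (!is.null(be)) as.integer(be[3]) else NA_integer_,
      at = list(at),
      wc = if ("WC" %in% names(vals)) vals[["WC"]] else NA_character_,
      wp = list(wp),
      lrt = if ("LRT" %in% names(vals))
        as.numeric(vals[["LRT"]]) else NA_real_,
      genotypes = list(gts))
  })
  dplyr::bind_rows(rows)
}
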