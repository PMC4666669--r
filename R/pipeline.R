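#' Indexed-FASTA accessor
#'
#' Wraps an indexed FASTA as a closure `function(chrom, start, end)`
#' returning the uppercase sequence over a 0-based half-open range. The
#' contig lengths are attached as the `"lengths"` attribute.
#'
#' @param path FASTA path (an `.fai` index is created when absent).
#' @return accessor function.
#' @export
fasta_accessor <- function(path) {
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  fa <- Rsamtools::FaFile(path)
  info <- Rsamtools::seqinfo(fa)
  lens <- stats::setNames(GenomeInfoDb::seqlengths(info),
                          GenomeInfoDb::seqnames(info))
  f <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    toupper(as.character(Rsamtools::getSeq(fa, gr)[[1]]))
  }
  attr(f, "lengths") <- lens
  f
}

empty_calls <- function() {
  tibble::tibble(chrom = character(), pos = integer(), side = character(),
                 support = integer(), be_chrom = character(),
                 be_pos = integer(), be_support = integer(),
                 mate_exact_support = integer(), n_split_chroms = integer(),
                 consensus = character(), at = list(), wc = character(),
                 wp = list(), lrt = numeric(), genotypes = list())
}

#' Call structural variant breakpoints jointly across samples
#'
#' The full calling pipeline: a genome-wide pass over every BAM collects
#' clip signatures into the joint clip index; positions where at least
#' `min_support` primary reads share a breakpoint become candidates; each
#' candidate's clipped overhangs are collapsed into a consensus (candidates
#' with consensus under 10 bp or over 50% column mismatch are discarded);
#' the partner breakpoint is located from SA/XA tag evidence, clustered on
#' a 10 bp grid and refined by Smith-Waterman realignment of the consensus;
#' translocations and >1 Mb events must show two reads at the exact partner
#' position and candidates whose split reads scatter over more than three
#' chromosomes are dropped; every sample is genotyped under the
#' mapping-quality bi-allelic model; sites where no single sample reaches
#' `min_alt` alternative reads are filtered; the fourteen pileup attributes
#' are extracted; and, when a background cohort is supplied, the binomial
#' likelihood-ratio `D` statistic contrasts target and background allele
#' frequencies. Two independent records are emitted per SV — one per
#' breakpoint — each carrying a `BE` pointer to its partner.
#'
#' The output is deterministic for fixed inputs regardless of `threads`.
#'
#' @param bams BAM paths of the (target) cohort.
#' @param reference reference FASTA path.
#' @param background_bams optional BAM paths of a background cohort;
#'   supplying them switches on the association test.
#' @param min_support minimum primary clipped reads defining a candidate.
#' @param min_alt joint-calling filter: at least one sample must have this
#'   many alternative-supporting reads.
#' @param sw Smith-Waterman parameters from [sw_params()].
#' @param window bp fetched around each candidate for evidence collection.
#' @param threads worker count for the per-candidate stage.
#' @param classifier optional `sv_classifier` used to annotate `WC`/`WP`.
#' @param out_vcf optional output VCF path.
#' @return a `clipsv_calls` tibble, one row per breakpoint record.
#' @export
sv_call <- function(bams, reference, background_bams = NULL,
                    min_support = 3L, min_alt = 3L, sw = sw_params(),
                    window = 1000L, threads = 1L, classifier = NULL,
                    out_vcf = NULL) {
  ref_fetch <- fasta_accessor(reference)
  contig_lens <- attr(ref_fetch, "lengths")

  all_bams <- c(bams, background_bams)
  csv_msg("pass 1: scanning ", length(all_bams), " BAM file(s)")
  pass1 <- purrr::map(all_bams, pass1_clip_scan)
  bam_samples <- vapply(pass1, `[[`, character(1), "sample_id")
  target_samples <- unique(bam_samples[seq_along(bams)])
  background_samples <- if (length(background_bams)) {
    setdiff(unique(bam_samples[-seq_along(bams)]), target_samples)
  } else character()
  samples <- unique(bam_samples[!is.na(bam_samples)])

  istats <- lapply(stats::setNames(nm = samples), function(s) {
    tl <- unlist(lapply(pass1[bam_samples == s], `[[`, "tlen_sample"))
    if (!length(tl)) return(c(mu = 400, sigma = 50))
    c(mu = stats::median(tl), sigma = max(stats::mad(tl), 1))
  })
  pooled_istats <- c(mu = stats::median(vapply(istats, `[[`, 0, "mu")),
                     sigma = stats::median(vapply(istats, `[[`, 0,
                                                  "sigma")))

  sigs <- dplyr::bind_rows(lapply(pass1, `[[`, "sigs"))
  rm(pass1); gc(verbose = FALSE)
  index <- build_clip_index(sigs)
  cands <- find_candidates(index, min_support = min_support)
  csv_msg(nrow(cands), " breakpoint candidate(s) with support >= ",
          min_support)
  if (!nrow(cands)) {
    calls <- empty_calls()
    if (!is.null(out_vcf)) {
      write_sv_vcf(calls, samples, basename(reference), out_vcf)
    }
    class(calls) <- c("clipsv_calls", class(calls))
    return(calls)
  }
  # per-sample primary clip support per candidate key
  key_support <- index %>%
    dplyr::filter(.data$is_primary) %>%
    dplyr::count(.data$chrom, pos = .data$break_pos, .data$side,
                 .data$sample_id, name = "sp")

  # evidence windows around candidates, coalesced, one fetch per BAM
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cands$chrom, IRanges::IRanges(pmax(cands$pos - window, 0L) + 1L,
                                  cands$pos + window)),
    min.gapwidth = 200L)
  regional <- dplyr::bind_rows(purrr::map(
    all_bams, read_alignments, region = gr, with_seq = TRUE,
    with_qname = TRUE))
  regional <- dplyr::distinct(regional, .data$qname, .data$chrom,
                              .data$pos, .data$cigar, .data$tlen,
                              .data$reverse, .keep_all = TRUE)
  regional <- dplyr::arrange(regional, .data$chrom, .data$pos)
  reg_by_chrom <- split(regional, regional$chrom)

  process_one <- function(i) {
    cand <- cands[i, ]
    process_candidate(cand, reg_by_chrom[[cand$chrom]], key_support,
                      istats, pooled_istats, ref_fetch, contig_lens, sw,
                      min_alt, samples)
  }
  rows <- if (threads > 1L) {
    parallel::mclapply(seq_len(nrow(cands)), process_one,
                       mc.cores = threads)
  } else {
    lapply(seq_len(nrow(cands)), process_one)
  }
  calls <- dplyr::bind_rows(rows)
  if (!nrow(calls)) calls <- empty_calls()

  if (nrow(calls)) {
    dist <- apply_distance_filters(calls)
    calls <- calls[dist$keep, , drop = FALSE]
  }

  if (nrow(calls) && length(background_samples)) {
    calls$lrt <- vapply(calls$genotypes, function(g) {
      cts <- assoc_counts(g, target_samples, background_samples)
      if (cts$k_t < 1 || cts$k_b < 1) return(NA_real_)
      lrt_statistic(cts$n_t, cts$k_t, cts$n_b, cts$k_b)
    }, numeric(1))
  }

  if (!is.null(classifier) && nrow(calls)) {
    calls <- classify_calls(calls, classifier)
  }

  calls <- dplyr::arrange(calls, .data$chrom, .data$pos, .data$side)
  if (!is.null(out_vcf)) {
    write_sv_vcf(calls, samples, basename(reference), out_vcf)
  }
  class(calls) <- unique(c("clipsv_calls", class(calls)))
  calls
}

# Genome-wide first pass over one BAM: clip signatures plus an
# insert-size sample. Streams per chromosome when an index is present so
# only one contig's records are in memory at a time.
pass1_clip_scan <- function(bam_path, max_tlen_sample = 1e5) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]
  sample_id <- header_sample_id(hdr, bam_path)
  targets <- hdr$targets
  chunks <- if (!is.na(bam_index_path(bam_path)) && length(targets)) {
    lapply(names(targets), function(cn)
      GenomicRanges::GRanges(cn, IRanges::IRanges(1L, targets[[cn]])))
  } else {
    list(NULL)   # no index: one whole-file scan
  }
  sig_list <- vector("list", length(chunks))
  tl <- integer()
  for (i in seq_along(chunks)) {
    reads <- read_alignments(bam_path, region = chunks[[i]],
                             with_seq = FALSE, with_tags = FALSE,
                             sample_id = sample_id)
    if (length(tl) < max_tlen_sample) {
      keep <- reads$proper_pair & !is.na(reads$tlen) & reads$tlen > 0
      tl <- c(tl, utils::head(reads$tlen[keep],
                              max_tlen_sample - length(tl)))
    }
    clipped <- !reads$unmapped & !reads$duplicate &
      (reads$clip_left_len > 0L | reads$clip_right_len > 0L)
    sig_list[[i]] <- clip_signatures(reads[clipped, , drop = FALSE])
    rm(reads)
  }
  list(sample_id = sample_id, sigs = dplyr::bind_rows(sig_list),
       tlen_sample = tl)
}

# everything that happens to one breakpoint candidate; returns a one-row
# calls tibble or NULL when a filter removes the candidate
process_candidate <- function(cand, regional, key_support, istats,
                              pooled_istats, ref_fetch, contig_lens, sw,
                              min_alt, samples) {
  if (is.null(regional) || !nrow(regional)) return(NULL)
  pos <- cand$pos
  starts <- regional$pos   # regional is a single chromosome, pos-sorted
  lo <- findInterval(pos - 350L, starts) + 1L
  hi <- findInterval(pos + 150L, starts)
  if (hi < lo) return(NULL)
  sub <- regional[lo:hi, , drop = FALSE]
  sub_end <- sub$pos + sub$ref_span

  sig_rows <- !sub$duplicate & !sub$secondary & !sub$supplementary &
    (if (cand$side == "left") sub$clip_left_len > 0L & sub$pos == pos
     else sub$clip_right_len > 0L & sub_end == pos)
  support_reads <- sub[sig_rows, , drop = FALSE]
  if (!nrow(support_reads)) return(NULL)

  clip_seqs <- if (cand$side == "left") {
    substr(support_reads$seq, 1L, support_reads$clip_left_len)
  } else {
    nl <- nchar(support_reads$seq)
    substr(support_reads$seq, nl - support_reads$clip_right_len + 1L, nl)
  }
  clip_seqs[is.na(support_reads$seq)] <- ""
  cons <- build_consensus(clip_seqs, cand$side)
  fc <- filter_consensus(cons$sequence, cons$mismatch_fraction)
  if (!fc$keep) return(NULL)

  eps <- candidate_endpoints(support_reads, cand$side, pooled_istats)
  cl <- cluster_endpoints(eps)
  if (nrow(cl)) {
    win <- cl[1, ]
    refined <- NA_integer_
    if (win$precise) {
      refined <- refine_with_sw(cons$sequence, ref_fetch, win$chrom,
                                win$rounded_pos, cand$side,
                                contig_lens[[win$chrom]], sw)
    }
    members <- win$member_positions[[1]]
    if (!is.na(refined)) {
      be_pos <- refined
      mate_exact <- sum(members == refined)
    } else {
      be_pos <- win$rounded_pos
      mate_exact <- max(tabulate(factor(members)))
    }
    be_chrom <- win$chrom
    be_support <- win$support
  } else {
    be_chrom <- NA_character_; be_pos <- NA_integer_
    be_support <- 0L; mate_exact <- 0L
  }
  sa_chroms <- unique(parse_tags_many(support_reads$sa)$chrom)
  n_split_chroms <- length(unique(c(cand$chrom, sa_chroms)))

  # pileup membership: reads covering the position, plus reads whose clip
  # boundary sits exactly on it (their aligned span ends at the
  # breakpoint but they are the very evidence that defines it)
  overlapping <- (sub$pos <= pos & sub_end > pos) |
    (sub$clip_right_len > 0L & sub_end == pos) |
    (sub$clip_left_len > 0L & sub$pos == pos)
  at <- extract_attributes(sub[overlapping, , drop = FALSE], pooled_istats)
  depth <- at$depth
  at_vec <- stats::setNames(as.numeric(at[1, attribute_names()]),
                            attribute_names())

  gts <- lapply(stats::setNames(nm = samples), function(s) {
    ev <- classify_read_evidence(sub[sub$sample_id == s, , drop = FALSE],
                                 cand$chrom, pos, be_chrom, be_pos,
                                 istats[[s]] %||% pooled_istats)
    genotype_likelihoods(ev)
  })
  alt_counts <- vapply(gts, `[[`, 0L, "alt_count")
  if (!joint_site_filter(alt_counts, min_alt)) return(NULL)

  ks <- key_support[key_support$chrom == cand$chrom &
                      key_support$pos == pos &
                      key_support$side == cand$side, ]
  gtab <- dplyr::bind_rows(gts)
  gtab$sample_id <- names(gts)
  gtab$sp <- ks$sp[match(gtab$sample_id, ks$sample_id)]
  gtab$sp[is.na(gtab$sp)] <- 0L

  tibble::tibble(
    chrom = cand$chrom, pos = pos, side = cand$side,
    support = cand$support, be_chrom = be_chrom, be_pos = be_pos,
    be_support = be_support, mate_exact_support = mate_exact,
    n_split_chroms = n_split_chroms, consensus = cons$sequence,
    at = list(at_vec), wc = NA_character_, wp = list(NULL),
    lrt = NA_real_, genotypes = list(gtab))
}

#' Annotate an existing VCF with SV types
#'
#' Reads a VCF carrying `AT` attribute vectors, classifies every record
#' with the supplied (or freshly trained) random forest and rewrites the
#' file with `WC`/`WP` added. Nothing else about the records changes, so
#' re-classifying an already-classified file with the same model is a
#' no-op. Records without an `AT` field pass through with `WC=UNK` and a
#' warning.
#'
#' @param vcf_in input VCF path.
#' @param vcf_out output VCF path.
#' @param model an `sv_classifier`, or `NULL` to train one from
#'   `training`.
#' @param training training-file path (see [read_training_file()]) used
#'   when `model` is `NULL`.
#' @param seed seed for training.
#' @return the classified calls tibble, invisibly.
#' @export
run_classify <- function(vcf_in, vcf_out, model = NULL, training = NULL,
                         seed = 1L) {
  if (is.null(model)) {
    if (is.null(training)) {
      stop("supply either a fitted model or a training file",
           call. = FALSE)
    }
    model <- train_sv_classifier(read_training_file(training), seed = seed)
  }
  calls <- read_sv_vcf(vcf_in)
  hdr <- readLines(vcf_in)
  samples <- strsplit(grep("^#CHROM", hdr, value = TRUE),
                      "\t", fixed = TRUE)[[1]]
  samples <- if (length(samples) > 9) samples[-(1:9)] else character()
  ref_line <- grep("^##reference=", hdr, value = TRUE)
  refname <- if (length(ref_line)) sub("^##reference=", "", ref_line[1])
    else "unknown"
  if (nrow(calls)) calls <- classify_calls(calls, model)
  write_sv_vcf(calls, samples, refname, vcf_out)
  invisible(calls)
}

#' Benchmark a call VCF against a truth BED
#'
#' Thin wrapper over [evaluate_calls()]: reads the calls and the truth
#' intervals, scores them at the requested slop and optionally writes the
#' per-stratum table as TSV.
#'
#' @param calls_vcf VCF path.
#' @param truth_bed truth-interval BED path (see [write_truth_bed()]).
#' @param slop bp added to both ends of each truth interval.
#' @param out_tsv optional TSV output path.
#' @return a `clipsv_bench` tibble.
#' @export
run_bench <- function(calls_vcf, truth_bed, slop = 0L, out_tsv = NULL) {
  calls <- read_sv_vcf(calls_vcf)
  ints <- read_truth_bed(truth_bed)
  res <- evaluate_calls(calls, ints, slop = slop)
  if (!is.null(out_tsv)) {
    utils::write.table(res, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
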