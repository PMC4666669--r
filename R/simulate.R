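#' Simulation configuration
#'
#' Bundles every knob of the synthetic dataset: genome shape, SV load and
#' size law, library geometry and evidence-emission behaviour. The seed is
#' mandatory — every downstream stage derives its randomness from it, and
#' all outputs are byte-identical per seed.
#'
#' @param seed integer seed (required).
#' @param n_chroms number of synthetic contigs.
#' @param chrom_length length of each contig in bp.
#' @param n_svs_per_class SVs implanted per class.
#' @param sv_classes SV classes to implant (subset of DEL, DUP, INS, INV).
#' @param size_range SV size range in bp; sizes are drawn log-uniformly
#'   over this range (truncated to what the contigs can hold) so small
#'   variants dominate, mirroring the empirical SV size distribution.
#' @param coverage haploid-genome read coverage (e.g. 10 or 50).
#' @param read_length read length in bp.
#' @param insert_mu,insert_sigma mean/sd of the fragment-length
#'   distribution.
#' @param base_error_rate per-base substitution error rate injected into
#'   emitted sequences.
#' @param clip_fraction probability that a breakpoint-crossing read is
#'   emitted with its clip evidence (the remainder are emitted aligned to
#'   their anchor only, emulating an aligner absorbing a short overhang).
#' @param min_sa_clip minimum clipped-portion length for an SA entry to be
#'   emitted (shorter overhangs are soft-clipped without a split-read
#'   record, as short split alignments are unreliable).
#' @param spurious_clip_rate probability that an ordinary read picks up an
#'   artefactual soft clip of random sequence (chimera/adapter noise).
#' @param n_samples number of diploid samples.
#' @param hom_fraction probability an implanted SV is homozygous in a
#'   carrier sample.
#' @param min_gap minimum distance between implanted SVs in bp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_chroms = 10L, chrom_length = 2e6,
                       n_svs_per_class = 100L,
                       sv_classes = c("DEL", "DUP", "INS", "INV"),
                       size_range = c(50, 1e6), coverage = 50,
                       read_length = 100L, insert_mu = 400,
                       insert_sigma = 50, base_error_rate = 0.001,
                       clip_fraction = 1.0, min_sa_clip = 20L,
                       spurious_clip_rate = 0.002, n_samples = 1L,
                       hom_fraction = 0.5, min_gap = 1000L) {
  if (missing(seed)) stop("sim_config() requires a seed", call. = FALSE)
  stopifnot(n_chroms >= 1, chrom_length > 0, coverage > 0, read_length > 0,
            size_range[1] >= 1, size_range[2] >= size_range[1])
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_svs_per_class = as.integer(n_svs_per_class),
    sv_classes = sv_classes, size_range = size_range, coverage = coverage,
    read_length = as.integer(read_length), insert_mu = insert_mu,
    insert_sigma = insert_sigma, base_error_rate = base_error_rate,
    clip_fraction = clip_fraction, min_sa_clip = as.integer(min_sa_clip),
    spurious_clip_rate = spurious_clip_rate,
    n_samples = as.integer(n_samples), hom_fraction = hom_fraction,
    min_gap = as.integer(min_gap)), class = "sim_config")
}

sim_sample_ids <- function(config) paste0("s", seq_len(config$n_samples))

#' Generate a seeded random reference genome
#'
#' Contigs of i.i.d. uniform A/C/G/T named `chr01`, `chr02`, ... —
#' deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return a named `Biostrings::DNAStringSet`.
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  seqs <- vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("chr%02d", seq_len(config$n_chroms))
  out
}

#' Implant structural variants and assign zygosities
#'
#' Places `n_svs_per_class` variants of each configured class on the
#' reference, non-overlapping and at least `min_gap` apart, with sizes
#' drawn log-uniformly. Placement is by rejection sampling: a draw that
#' cannot be placed (the genome is too full for it) has its size redrawn,
#' so the realised size distribution is the log-uniform law conditioned on
#' fitting the genome. Insertions copy a donor interval from another
#' chromosome to a recipient point (inter-chromosomal copy events); the
#' donor interval is also reserved so no other SV overlaps it. Each
#' carrier sample is homozygous with probability `hom_fraction`, otherwise
#' heterozygous on a random haplotype.
#'
#' @param reference `DNAStringSet` from [simulate_reference()].
#' @param config a [sim_config()].
#' @return truth tibble: `sv_id`, `sv_class`, `chrom`, `start`, `end`
#'   (0-based half-open; `start == end` = insertion point), `size`,
#'   `donor_chrom`, `donor_start`, `donor_end`, and per-sample list
#'   columns `zygosity` and `het_hap`.
#' @export
implant_svs <- function(reference, config) {
  lens <- Biostrings::width(reference)   # force before seeding: a lazily
  nms <- names(reference)                # evaluated simulate_reference()
  set.seed(config$seed + 1L)             # call would reset the RNG
  nC <- length(reference)
  occ <- lapply(seq_len(nC), function(i) IRanges::IRanges())
  gap <- config$min_gap

  free_at <- function(ci, start, end) {
    q <- IRanges::IRanges(max(0L, start - gap) + 1L, end + gap)
    IRanges::countOverlaps(q, occ[[ci]]) == 0L
  }
  reserve <- function(ci, start, end) {
    occ[[ci]] <<- c(occ[[ci]], IRanges::IRanges(start + 1L, max(end, start + 1L)))
  }
  draw_size <- function(smax) {
    as.integer(round(exp(stats::runif(1, log(config$size_range[1]),
                                      log(max(config$size_range[1],
                                              smax))))))
  }

  n_total <- config$n_svs_per_class * length(config$sv_classes)
  samples <- sim_sample_ids(config)
  if (n_total == 0L) {
    return(tibble::tibble(
      sv_id = character(), sv_class = character(), chrom = character(),
      start = integer(), end = integer(), size = integer(),
      donor_chrom = character(), donor_start = integer(),
      donor_end = integer(), zygosity = list(), het_hap = list()))
  }
  classes <- config$sv_classes[((seq_len(n_total) - 1L) %%
                                  length(config$sv_classes)) + 1L]
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cl <- classes[i]
    smax <- min(config$size_range[2], max(lens) - 2L * gap - 2L)
    placed <- FALSE
    for (redraw in 1:80) {
      size <- draw_size(smax)
      for (att in 1:40) {
        if (cl == "INS") {
          ci <- sample.int(nC, 1)
          di <- if (nC > 1) {
            others <- setdiff(seq_len(nC), ci)
            others[sample.int(length(others), 1)]
          } else ci
          if (size > lens[di] - 2L * gap - 2L) break
          p <- sample.int(lens[ci] - 2L * gap, 1) + gap - 1L
          ds <- sample.int(lens[di] - size - 2L * gap, 1) + gap - 1L
          if (free_at(ci, p, p + 1L) && free_at(di, ds, ds + size)) {
            reserve(ci, p, p + 1L); reserve(di, ds, ds + size)
            rows[[i]] <- tibble::tibble(
              sv_class = cl, chrom = nms[ci], start = p, end = p,
              size = size, donor_chrom = nms[di], donor_start = ds,
              donor_end = ds + size)
            placed <- TRUE
          }
        } else {
          ci <- sample.int(nC, 1)
          if (size > lens[ci] - 2L * gap - 2L) break
          s <- sample.int(lens[ci] - size - 2L * gap, 1) + gap - 1L
          if (free_at(ci, s, s + size)) {
            reserve(ci, s, s + size)
            rows[[i]] <- tibble::tibble(
              sv_class = cl, chrom = nms[ci], start = s, end = s + size,
              size = size, donor_chrom = NA_character_,
              donor_start = NA_integer_, donor_end = NA_integer_)
            placed <- TRUE
          }
        }
        if (placed) break
      }
      if (placed) break
      smax <- max(config$size_range[1], smax %/% 4L)  # genome filling up
    }
    if (!placed) {
      stop("reference too small for the requested SV load (failed at SV ",
           i, " of ", n_total, ")", call. = FALSE)
    }
  }
  truth <- dplyr::bind_rows(rows)
  truth$sv_id <- sprintf("sv%04d", seq_len(n_total))

  zyg <- matrix(sample(c("hom", "het"), n_total * length(samples),
                       replace = TRUE,
                       prob = c(config$hom_fraction,
                                1 - config$hom_fraction)),
                nrow = n_total)
  hap <- matrix(sample(1:2, n_total * length(samples), replace = TRUE),
                nrow = n_total)
  truth$zygosity <- lapply(seq_len(n_total), function(i)
    stats::setNames(zyg[i, ], samples))
  truth$het_hap <- lapply(seq_len(n_total), function(i)
    stats::setNames(hap[i, ], samples))
  dplyr::select(truth, "sv_id", dplyr::everything())
}

# Haplotype segment map: how one haplotype of one sample is stitched from
# reference intervals. Collinear neighbours are merged so that only true
# SV junctions remain as segment boundaries (a tandem duplication, e.g.,
# has exactly one junction: ...end | start...).
build_hap_map <- function(truth, sample_id, hap, chrom_names, lens) {
  carried <- vapply(seq_len(nrow(truth)), function(i) {
    z <- truth$zygosity[[i]][[sample_id]]
    z == "hom" || (z == "het" && truth$het_hap[[i]][[sample_id]] == hap)
  }, logical(1))
  svs <- truth[carried, , drop = FALSE]

  maps <- lapply(seq_along(chrom_names), function(ci) {
    cn <- chrom_names[ci]
    len <- lens[ci]
    rows <- svs[svs$chrom == cn, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    segs <- list()
    add <- function(rci, rs, re, strand) {
      if (re > rs) segs[[length(segs) + 1L]] <<-
          c(ref_ci = rci, ref_start = rs, ref_end = re,
            strand = if (strand == "+") 1L else -1L)
    }
    cur <- 0L
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      add(ci, cur, r$start, "+")
      if (r$sv_class == "DEL") {
        cur <- r$end
      } else if (r$sv_class == "DUP") {
        add(ci, r$start, r$end, "+"); add(ci, r$start, r$end, "+")
        cur <- r$end
      } else if (r$sv_class == "INV") {
        add(ci, r$start, r$end, "-")
        cur <- r$end
      } else if (r$sv_class == "INS") {
        di <- match(r$donor_chrom, chrom_names)
        add(di, r$donor_start, r$donor_end, "+")
        cur <- r$start
      }
    }
    add(ci, cur, len, "+")
    m <- do.call(rbind, segs)
    # merge reference-collinear neighbours (both forward, contiguous)
    keep <- rep(TRUE, nrow(m))
    for (j in seq_len(nrow(m))[-1]) {
      k <- max(which(keep[1:(j - 1)]))
      if (m[j, "strand"] == 1L && m[k, "strand"] == 1L &&
          m[j, "ref_ci"] == m[k, "ref_ci"] &&
          m[j, "ref_start"] == m[k, "ref_end"]) {
        m[k, "ref_end"] <- m[j, "ref_end"]
        keep[j] <- FALSE
      }
    }
    m <- m[keep, , drop = FALSE]
    seg_len <- m[, "ref_end"] - m[, "ref_start"]
    tibble::tibble(
      gen_ci = ci,
      hap_start = cumsum(c(0L, seg_len))[seq_len(nrow(m))],
      len = seg_len, ref_ci = m[, "ref_ci"],
      ref_start = m[, "ref_start"], ref_end = m[, "ref_end"],
      strand = m[, "strand"])
  })
  maps
}

# character haplotype sequence for one chrom of one hap map
hap_sequence <- function(reference, segs) {
  pieces <- lapply(seq_len(nrow(segs)), function(j) {
    s <- Biostrings::subseq(reference[[segs$ref_ci[j]]],
                            segs$ref_start[j] + 1L, segs$ref_end[j])
    if (segs$strand[j] == -1L) s <- Biostrings::reverseComplement(s)
    s
  })
  as.character(do.call(Biostrings::xscat, pieces))
}

# inject substitution errors into sequences at `rate` per base
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(length(s), min(n_err[i], length(s)))
    s[at] <- vapply(s[at], function(b)
      sample(setdiff(bases, b), 1), character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

random_dna <- function(n_chars) {
  vapply(n_chars, function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}

# Emit alignment records for one (sample, haplotype, chromosome).
# Returns a tibble of BAM-record fields in 0-based coordinates with
# integer chromosome indices; sequences only for records carrying clip
# evidence ("*" otherwise).
emit_hap_reads <- function(hap_seq, segs, config, frag_prefix) {
  rl <- config$read_length
  hl <- nchar(hap_seq)
  nf <- round(hl * config$coverage / (4 * rl))
  if (nf < 1) return(NULL)
  fl <- as.integer(pmin(pmax(round(stats::rnorm(nf, config$insert_mu,
                                                config$insert_sigma)),
                             2L * rl + 10L),
                        round(config$insert_mu +
                                4 * config$insert_sigma)))
  fs <- as.integer(floor(stats::runif(nf, 0, hl - fl)))
  a <- c(fs, fs + fl - rl)          # read start on hap (R1 then R2)
  b <- a + rl
  hap_fwd <- rep(c(TRUE, FALSE), each = nf)
  nr <- 2L * nf

  seg_starts <- segs$hap_start
  i1 <- findInterval(a, seg_starts)
  i2 <- findInterval(b - 1L, seg_starts)

  ci <- integer(nr); pos <- integer(nr); span <- integer(nr)
  rev <- logical(nr); cig <- character(nr); seq_out <- rep(NA_character_, nr)
  sa <- rep(NA_character_, nr); need_rc <- logical(nr)

  simple <- i1 == i2
  si <- which(simple)
  sidx <- i1[si]
  minus <- segs$strand[sidx] == -1L
  off <- a[si] - segs$hap_start[sidx]
  ci[si] <- segs$ref_ci[sidx]
  pos[si] <- ifelse(minus,
                    segs$ref_start[sidx] + (segs$len[sidx] - off - rl),
                    segs$ref_start[sidx] + off)
  span[si] <- rl
  rev[si] <- hap_fwd[si] == minus
  cig[si] <- paste0(rl, "M")

  cigar_clip <- function(l, m, r) {
    paste0(ifelse(l > 0, paste0(l, "S"), ""), m, "M",
           ifelse(r > 0, paste0(r, "S"), ""))
  }

  for (idx in which(!simple)) {
    ss <- i1[idx]:i2[idx]
    ps <- pmax(a[idx], segs$hap_start[ss])
    pe <- pmin(b[idx], segs$hap_start[ss] + segs$len[ss])
    plen <- pe - ps
    k <- which.max(plen)
    srow <- ss[k]
    minus_k <- segs$strand[srow] == -1L
    rs <- if (minus_k) {
      segs$ref_start[srow] + (segs$hap_start[srow] + segs$len[srow] - pe[k])
    } else {
      segs$ref_start[srow] + (ps[k] - segs$hap_start[srow])
    }
    ci[idx] <- segs$ref_ci[srow]
    pos[idx] <- rs
    span[idx] <- plen[k]
    rev[idx] <- hap_fwd[idx] == minus_k
    clip_hap_l <- ps[k] - a[idx]
    clip_hap_r <- b[idx] - pe[k]
    if (stats::runif(1) > config$clip_fraction) {
      # aligner absorbed the overhang: anchor only, no clip evidence
      cig[idx] <- paste0(plen[k], "M")
      span[idx] <- plen[k]
      next
    }
    if (minus_k) {
      cl <- clip_hap_r; cr <- clip_hap_l
    } else {
      cl <- clip_hap_l; cr <- clip_hap_r
    }
    cig[idx] <- cigar_clip(cl, plen[k], cr)
    seq_out[idx] <- substr(hap_seq, a[idx] + 1L, b[idx])
    need_rc[idx] <- minus_k   # batch-reverse-complemented below
    # SA entries for adjacent portions long enough to have been split-mapped
    sa_entries <- character()
    for (j in c(k - 1L, k + 1L)) {
      if (j < 1L || j > length(ss)) next
      if (plen[j] < config$min_sa_clip) next
      jrow <- ss[j]
      minus_j <- segs$strand[jrow] == -1L
      rs_j <- if (minus_j) {
        segs$ref_start[jrow] + (segs$hap_start[jrow] + segs$len[jrow] - pe[j])
      } else {
        segs$ref_start[jrow] + (ps[j] - segs$hap_start[jrow])
      }
      rev_j <- hap_fwd[idx] == minus_j
      pre <- if (minus_j) b[idx] - pe[j] else ps[j] - a[idx]
      sa_entries <- c(sa_entries, sprintf(
        "%s,%d,%s,%s,60,0;", sprintf("chr%02d", segs$ref_ci[jrow]),
        rs_j + 1L, if (rev_j) "-" else "+",
        cigar_clip(pre, plen[j], rl - pre - plen[j])))
    }
    if (length(sa_entries)) sa[idx] <- paste(sa_entries, collapse = "")
  }

  rc <- which(need_rc & !is.na(seq_out))
  if (length(rc)) seq_out[rc] <- revcomp(seq_out[rc])

  # artefactual clips on ordinary reads (chimera / adapter noise)
  spur <- which(simple & stats::runif(nr) < config$spurious_clip_rate)
  if (length(spur)) {
    clen <- sample(5:30, length(spur), replace = TRUE)
    left <- stats::runif(length(spur)) < 0.5
    rseq <- substring(hap_seq, a[spur] + 1L, b[spur])
    minus_s <- segs$strand[i1[spur]] == -1L
    if (any(minus_s)) rseq[minus_s] <- revcomp(rseq[minus_s])
    junk <- random_dna(clen)
    cig[spur] <- ifelse(left,
                        paste0(clen, "S", rl - clen, "M"),
                        paste0(rl - clen, "M", clen, "S"))
    pos[spur] <- pos[spur] + ifelse(left, clen, 0L)
    seq_out[spur] <- ifelse(left,
                            paste0(junk, substring(rseq, clen + 1L, rl)),
                            paste0(substring(rseq, 1L, rl - clen), junk))
    span[spur] <- rl - clen
  }

  has_seq <- !is.na(seq_out)
  seq_out[has_seq] <- mutate_seqs(seq_out[has_seq], config$base_error_rate)

  # mate fields and template length
  m <- c(nf + seq_len(nf), seq_len(nf))   # index of each read's mate
  mate_ci <- ci[m]; mate_pos <- pos[m]; mate_rev <- rev[m]
  same <- ci == mate_ci
  lo <- pmin(pos, mate_pos)
  hi <- pmax(pos + span, mate_pos + span[m])
  tl <- ifelse(same, ifelse(pos < mate_pos | (pos == mate_pos & !rev),
                            hi - lo, -(hi - lo)), 0L)
  proper <- same & (rev != mate_rev) &
    abs(tl) <= config$insert_mu + 3 * config$insert_sigma &
    ifelse(rev, mate_pos <= pos, pos <= mate_pos)
  flag <- 1L + 2L * proper + 16L * rev + 32L * mate_rev +
    ifelse(hap_fwd, 64L, 128L)

  tibble::tibble(
    frag = paste0(frag_prefix, rep(seq_len(nf), 2)),
    flag = flag, ci = ci, pos = as.integer(pos), mapq = 60L, cigar = cig,
    mate_ci = mate_ci, mate_pos = as.integer(mate_pos),
    tlen = as.integer(tl), seq = seq_out, sa = sa)
}

#' Emit the alignment-level evidence of one sample as a sorted BAM
#'
#' Tiles both haplotypes of the sample with proper pairs at the configured
#' coverage. Reads crossing an SV junction are emitted soft-clipped at the
#' junction with an `SA` tag pointing at the partner locus (strand-flipped
#' across inversion junctions, inter-chromosomal for insertion events);
#' insert sizes are Normal(mu, sigma); substitution errors are injected at
#' `base_error_rate`; a small rate of artefactual soft clips emulates
#' chimeric read noise. Sequences are stored for clip-carrying records
#' ("*" otherwise — the caller only consumes sequence from clipped reads).
#' The SAM text is converted, coordinate-sorted and indexed with
#' `Rsamtools::asBam`.
#'
#' @param reference `DNAStringSet`.
#' @param truth truth tibble from [implant_svs()].
#' @param config a [sim_config()].
#' @param sample_id one of the configured sample ids.
#' @param out_prefix output path prefix (the BAM lands at
#'   `<out_prefix>.bam`).
#' @return path to the BAM file.
#' @export
emit_alignments <- function(reference, truth, config, sample_id,
                            out_prefix) {
  chrom_names <- names(reference)   # force arguments before seeding
  lens <- Biostrings::width(reference)
  force(truth)
  sample_no <- match(sample_id, sim_sample_ids(config))
  set.seed(config$seed + 1000L * sample_no)

  recs <- list()
  for (hap in 1:2) {
    maps <- build_hap_map(truth, sample_id, hap, chrom_names, lens)
    for (ci in seq_along(maps)) {
      segs <- maps[[ci]]
      hseq <- hap_sequence(reference, segs)
      recs[[length(recs) + 1L]] <- emit_hap_reads(
        hseq, segs, config, sprintf("s%dh%dc%02df", sample_no, hap, ci))
      rm(hseq)
    }
  }
  recs <- dplyr::bind_rows(recs)
  write_sim_bam(recs, chrom_names, lens, sample_id, out_prefix)
}

write_sim_bam <- function(recs, chrom_names, lens, sample_id, out_prefix) {
  # records are written in generation order; asBam coordinate-sorts
  sam_path <- paste0(out_prefix, ".sam")
  con <- file(sam_path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom_names, lens),
               sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id)), con)
  n <- nrow(recs)
  chunk <- 2e6
  for (s in seq(1L, max(n, 1L), by = chunk)) {
    if (!n) break
    e <- min(s + chunk - 1L, n)
    r <- recs[s:e, ]
    rname <- chrom_names[r$ci]
    rnext <- ifelse(r$mate_ci == r$ci, "=", chrom_names[r$mate_ci])
    satag <- ifelse(is.na(r$sa), "", paste0("\tSA:Z:", r$sa))
    lines <- paste0(r$frag, "\t", r$flag, "\t", rname, "\t", r$pos + 1L,
                    "\t", r$mapq, "\t", r$cigar, "\t", rnext, "\t",
                    r$mate_pos + 1L, "\t", r$tlen, "\t",
                    ifelse(is.na(r$seq), "*", r$seq), "\t*\tRG:Z:",
                    sample_id, satag)
    writeLines(lines, con)
  }
  close(con)
  on.exit()
  bam <- Rsamtools::asBam(sam_path, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam_path)
  bam
}

#' Generate a complete simulated dataset on disk
#'
#' Reference FASTA (+ index), truth table (TSV), truth-interval BED
#' (25 bp each side of every breakpoint) and one sorted, indexed BAM per
#' sample.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param pad truth-interval padding in bp (default 25).
#' @return list with `config`, `truth`, `reference` (path), `bams`
#'   (named paths), `truth_bed`, `truth_tsv`.
#' @export
simulate_sv_dataset <- function(config, out_dir, pad = 25L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  ref_path <- file.path(out_dir, "ref.fa")
  Biostrings::writeXStringSet(reference, ref_path)
  Rsamtools::indexFa(ref_path)

  truth <- implant_svs(reference, config)
  bed_path <- file.path(out_dir, "truth.bed")
  write_truth_bed(truth, bed_path, pad = pad)
  tsv_path <- file.path(out_dir, "truth.tsv")
  write_truth_tsv(truth, tsv_path)

  samples <- sim_sample_ids(config)
  bams <- vapply(samples, function(s) {
    emit_alignments(reference, truth, config, s, file.path(out_dir, s))
  }, character(1))

  list(config = config, truth = truth, reference = ref_path,
       bams = bams, truth_bed = bed_path, truth_tsv = tsv_path)
}

#' Write simulated reads as FASTQ
#'
#' Optional raw-read emitter for users who want to run a real aligner over
#' the simulated haplotypes instead of using the alignment-level evidence
#' of [emit_alignments()]. Mates are written to `_1.fq` / `_2.fq` with
#' constant quality.
#'
#' @param reference `DNAStringSet`.
#' @param truth truth tibble.
#' @param config a [sim_config()].
#' @param sample_id sample to emit.
#' @param out_prefix output path prefix.
#' @return named paths of the two FASTQ files.
#' @export
write_sim_fastq <- function(reference, truth, config, sample_id,
                            out_prefix) {
  chrom_names <- names(reference)   # force arguments before seeding
  lens <- Biostrings::width(reference)
  force(truth)
  sample_no <- match(sample_id, sim_sample_ids(config))
  set.seed(config$seed + 2000L * sample_no)
  rl <- config$read_length
  p1 <- paste0(out_prefix, "_1.fq"); p2 <- paste0(out_prefix, "_2.fq")
  c1 <- file(p1, "wt"); c2 <- file(p2, "wt")
  on.exit({ close(c1); close(c2) }, add = TRUE)
  for (hap in 1:2) {
    maps <- build_hap_map(truth, sample_id, hap, chrom_names, lens)
    for (ci in seq_along(maps)) {
      segs <- maps[[ci]]
      hseq <- hap_sequence(reference, segs)
      hl <- nchar(hseq)
      nf <- round(hl * config$coverage / (4 * rl))
      if (nf < 1) next
      fl <- pmin(pmax(round(stats::rnorm(nf, config$insert_mu,
                                         config$insert_sigma)),
                      2L * rl + 10L),
                 round(config$insert_mu + 4 * config$insert_sigma))
      fs <- floor(stats::runif(nf, 0, hl - fl))
      r1 <- mutate_seqs(substr(rep(hseq, nf), fs + 1L, fs + rl),
                        config$base_error_rate)
      r2 <- mutate_seqs(revcomp(substr(rep(hseq, nf), fs + fl - rl + 1L,
                                       fs + fl)),
                        config$base_error_rate)
      ids <- sprintf("@s%dh%dc%02df%d", sample_no, hap, ci, seq_len(nf))
      q <- strrep("I", rl)
      writeLines(paste(ids, r1, "+", q, sep = "\n"), c1)
      writeLines(paste(ids, r2, "+", q, sep = "\n"), c2)
    }
  }
  c(r1 = p1, r2 = p2)
}

#' Write / read the truth table
#'
#' Plain TSV with one row per SV; zygosity and haplotype assignments are
#' flattened to per-sample columns.
#'
#' @param truth truth tibble.
#' @param path file path.
#' @return `read_truth_tsv()` returns the truth tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  samples <- if (nrow(truth)) names(truth$zygosity[[1]]) else character()
  flat <- truth[, c("sv_id", "sv_class", "chrom", "start", "end", "size",
                    "donor_chrom", "donor_start", "donor_end")]
  for (s in samples) {
    flat[[paste0("zyg_", s)]] <-
      vapply(truth$zygosity, `[[`, character(1), s)
    flat[[paste0("hap_", s)]] <-
      vapply(truth$het_hap, `[[`, numeric(1), s)
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  flat <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  samples <- sub("^zyg_", "", grep("^zyg_", names(flat), value = TRUE))
  out <- tibble::as_tibble(
    flat[, c("sv_id", "sv_class", "chrom", "start", "end", "size",
             "donor_chrom", "donor_start", "donor_end")])
  out$zygosity <- lapply(seq_len(nrow(flat)), function(i)
    stats::setNames(vapply(samples, function(s)
      as.character(flat[[paste0("zyg_", s)]][i]), character(1)), samples))
  out$het_hap <- lapply(seq_len(nrow(flat)), function(i)
    stats::setNames(vapply(samples, function(s)
      as.numeric(flat[[paste0("hap_", s)]][i]), numeric(1)), samples))
  out
}
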