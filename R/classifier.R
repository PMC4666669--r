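#' Train the random-forest SV-type classifier
#'
#' Fits a random forest over the fourteen depth-normalised pileup
#' attributes to predict the SV class. Accuracy is first estimated by
#' stratified k-fold cross-validation (each class split evenly across
#' folds, deterministic under the seed), then the final model is refit on
#' all rows. Labels beyond the canonical four (`DEL`, `DUP`, `INS`,
#' `INV`) are allowed, so users can retrain with their own classes,
#' including an explicit false-positive class.
#'
#' @param training tibble/data.frame with the 14 attribute columns (in
#'   [attribute_names()] order) and a final `label` column, as produced by
#'   [read_training_file()].
#' @param seed integer seed; required for reproducible forests.
#' @param k number of cross-validation folds (default 5).
#' @param ntree forest size (default 200).
#' @return object of class `sv_classifier`: the fitted forest, class
#'   levels, `cv_accuracy`, and the training metadata.
#' @export
train_sv_classifier <- function(training, seed, k = 5L, ntree = 200L) {
  nm <- attribute_names()
  stopifnot(all(nm %in% names(training)), "label" %in% names(training))
  x <- as.data.frame(training[, nm])
  y <- as.character(training$label)
  tab <- table(y)
  short <- names(tab)[tab < k]
  if (length(short)) {
    stop("class ", paste(short, collapse = ", "), " has fewer than k = ",
         k, " training rows", call. = FALSE)
  }
  lv <- class_levels(unique(y))
  yf <- factor(y, levels = lv)

  set.seed(seed)
  # stratified folds: shuffle within class, deal out cyclically
  fold <- integer(length(yf))
  for (cl in lv) {
    idx <- sample(which(yf == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    rf <- randomForest::randomForest(x[fold != f, , drop = FALSE],
                                     yf[fold != f], ntree = ntree)
    mean(stats::predict(rf, x[fold == f, , drop = FALSE]) == yf[fold == f])
  }, numeric(1))

  set.seed(seed)
  rf <- randomForest::randomForest(x, yf, ntree = ntree, importance = TRUE)
  structure(list(forest = rf, classes = lv, cv_accuracy = mean(acc),
                 cv_fold_accuracy = acc, k = k, ntree = ntree, seed = seed,
                 n_training = nrow(x)),
            class = "sv_classifier")
}

# canonical four first, any user classes after, alphabetically
class_levels <- function(classes) {
  canon <- c("DEL", "DUP", "INS", "INV")
  c(canon[canon %in% classes], sort(setdiff(classes, canon)))
}

#' @export
print.sv_classifier <- function(x, ...) {
  cat("SV-type random forest (", x$ntree, " trees, ", x$n_training,
      " training rows)\n", sep = "")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("stratified %d-fold CV accuracy: %.3f\n", x$k, x$cv_accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the classifier's variable importances
#'
#' @param x an `sv_classifier`.
#' @param ... unused.
#' @return tibble with `attribute`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`.
#' @export
tidy.sv_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(
    attribute = rownames(imp),
    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
    mean_decrease_gini = imp[, "MeanDecreaseGini"]) %>%
    dplyr::arrange(dplyr::desc(.data$mean_decrease_gini))
}

#' One-row model summary
#'
#' @param x an `sv_classifier`.
#' @param ... unused.
#' @return one-row tibble: `n_training`, `n_classes`, `k`, `ntree`,
#'   `cv_accuracy`.
#' @export
glance.sv_classifier <- function(x, ...) {
  tibble::tibble(n_training = x$n_training,
                 n_classes = length(x$classes),
                 k = x$k, ntree = x$ntree, cv_accuracy = x$cv_accuracy)
}

#' Classify calls by SV type
#'
#' Annotates each call with `wc` (the most probable class) and `wp` (a
#' list column of per-class probabilities, canonical classes first).
#' Classification is post hoc: breakpoints, genotypes and association
#' statistics are never altered. Probability ties resolve to the earlier
#' class in the model's class order.
#'
#' @param calls calls tibble carrying an `at` list column of attribute
#'   vectors (as produced by the pipeline), or 14 attribute columns.
#' @param model an `sv_classifier`.
#' @return `calls` with `wc` and `wp` replaced/added.
#' @export
classify_calls <- function(calls, model) {
  stopifnot(inherits(model, "sv_classifier"))
  nm <- attribute_names()
  if ("at" %in% names(calls)) {
    x <- matrix(NA_real_, nrow(calls), 14, dimnames = list(NULL, nm))
    for (i in seq_len(nrow(calls))) {
      v <- calls$at[[i]]
      if (!is.null(v) && length(v) == 14L) x[i, ] <- as.numeric(v[nm])
    }
  } else {
    x <- as.matrix(calls[, nm])
  }
  missing_at <- !stats::complete.cases(x)
  if (any(!missing_at)) {
    xs <- x[!missing_at, , drop = FALSE]
    if (any(xs < 0 | xs > 1)) {
      stop("attribute values outside [0, 1]", call. = FALSE)
    }
    prob <- stats::predict(model$forest,
                           as.data.frame(xs), type = "prob")
  }
  wc <- rep("UNK", nrow(calls))
  wp <- vector("list", nrow(calls))
  j <- 1L
  for (i in seq_len(nrow(calls))) {
    if (missing_at[i]) {
      warning("call ", i, " has no attribute vector; WC set to UNK",
              call. = FALSE)
      wp[[i]] <- stats::setNames(rep(NA_real_, length(model$classes)),
                                 model$classes)
    } else {
      p <- prob[j, ]; j <- j + 1L
      wc[i] <- model$classes[which.max(p)]
      wp[[i]] <- stats::setNames(as.numeric(p), colnames(prob))
    }
  }
  calls$wc <- wc
  calls$wp <- wp
  calls
}

#' Attribute vectors at truth breakpoints, labelled by SV class
#'
#' Builds classifier training data from a simulated dataset: for every
#' truth SV the fourteen pileup attributes are extracted at each of its
#' breakpoints (recipient point and donor start for insertions) over the
#' combined pileup of all supplied BAMs, and labelled with the true
#' class.
#'
#' @param bams BAM paths.
#' @param truth truth tibble from [implant_svs()] / [read_truth_tsv()].
#' @param window bp fetched around each breakpoint.
#' @return tibble with the 14 attribute columns, `label`, `sv_id`,
#'   `chrom`, `pos`.
#' @export
truth_training_data <- function(bams, truth, window = 300L) {
  pts <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    if (r$sv_class == "INS") {
      tibble::tibble(sv_id = r$sv_id, label = r$sv_class,
                     chrom = c(r$chrom, r$donor_chrom),
                     pos = c(r$start, r$donor_start))
    } else {
      tibble::tibble(sv_id = r$sv_id, label = r$sv_class, chrom = r$chrom,
                     pos = c(r$start, r$end))
    }
  }))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    pts$chrom, IRanges::IRanges(pmax(pts$pos - window, 0L) + 1L,
                                pts$pos + window)), min.gapwidth = 100L)
  reads <- dplyr::bind_rows(purrr::map(bams, read_alignments, region = gr,
                                       with_seq = FALSE,
                                       with_qname = TRUE))
  reads <- dplyr::distinct(reads, .data$qname, .data$chrom, .data$pos,
                           .data$cigar, .data$tlen, .data$reverse,
                           .keep_all = TRUE)
  istats <- estimate_insert_stats(reads)
  by_chrom <- split(reads, reads$chrom)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    rc <- by_chrom[[pts$chrom[i]]]
    if (is.null(rc)) rc <- reads[0, ]
    rc_end <- rc$pos + rc$ref_span
    sel <- (rc$pos <= pts$pos[i] & rc_end > pts$pos[i]) |
      (rc$clip_right_len > 0L & rc_end == pts$pos[i]) |
      (rc$clip_left_len > 0L & rc$pos == pts$pos[i])
    extract_attributes(rc[sel, , drop = FALSE], istats)
  })
  out <- dplyr::bind_rows(rows)
  out$depth <- NULL
  dplyr::bind_cols(out, pts[, c("label", "sv_id", "chrom", "pos")])
}

#' Read / write the tab-delimited classifier training format
#'
#' Fifteen tab-separated columns: the fourteen attribute fractions in
#' [attribute_names()] order followed by the validated SV-type label.
#' Any label string is accepted so users may define their own classes.
#'
#' @param path file path.
#' @return `read_training_file()` returns a tibble with the 14 attribute
#'   columns plus `label`.
#' @export
read_training_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 15L)
  if (length(bad)) {
    stop("training file ", path, ": expected 15 tab-separated columns, ",
         "got ", lengths(parts)[bad[1]], " at line ", bad[1], call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 15L, byrow = TRUE)
  out <- tibble::as_tibble(as.data.frame(
    apply(m[, 1:14, drop = FALSE], 2, as.numeric)),
    .name_repair = "minimal")
  names(out) <- attribute_names()
  out$label <- m[, 15]
  out
}

#' @rdname read_training_file
#' @param training tibble with the 14 attribute columns and `label`.
#' @export
write_training_file <- function(training, path) {
  nm <- attribute_names()
  stopifnot(all(nm %in% names(training)), "label" %in% names(training))
  vals <- apply(as.matrix(training[, nm]), c(1, 2), fmt_num)
  lines <- paste(apply(vals, 1, paste, collapse = "\t"),
                 training$label, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
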