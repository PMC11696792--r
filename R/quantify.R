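#' Isoform fraction from qPCR threshold cycles
#'
#' Relative abundance of an isoform amplicon against the total transcript
#' measured in the same sample: `2^-(ct_isoform - ct_total)`. Replicate Ct
#' values should be averaged before calling (vectorised over both
#' arguments).
#'
#' @param ct_isoform Ct of the isoform-specific amplicon.
#' @param ct_total Ct of the total (all-isoform) amplicon, same sample.
#' @return the fraction `2^-dCt`.
#' @export
isoform_fraction <- function(ct_isoform, ct_total) {
  if (any(is.na(ct_isoform)) || any(is.na(ct_total)))
    stop("missing Ct value", call. = FALSE)
  if (any(ct_isoform <= 0) || any(ct_total <= 0))
    stop("Ct values must be positive", call. = FALSE)
  2^-(ct_isoform - ct_total)
}

#' Proportion isoform fractions into shares summing to one
#'
#' The per-amplicon fractions of overlapping amplicons need not sum to 1;
#' this post-hoc helper rescales a named vector of fractions into
#' "respective abundance"-style shares.
#'
#' @param fractions named numeric vector of per-isoform fractions.
#' @return shares summing to 1.
#' @export
isoform_shares <- function(fractions) fractions / sum(fractions)

#' Summarise a qPCR Ct table into isoform fractions
#'
#' @param ct data.frame with columns `sample, target, ct`; replicate rows
#'   are averaged per (sample, target).
#' @param total_target name of the total-transcript amplicon.
#' @return data.frame `sample, target, fraction` for all non-total targets.
#' @export
qpcr_fractions <- function(ct, total_target = "total") {
  stopifnot(all(c("sample", "target", "ct") %in% names(ct)))
  agg <- stats::aggregate(ct ~ sample + target, data = ct, FUN = mean)
  out <- list()
  for (s in unique(agg$sample)) {
    a <- agg[agg$sample == s, ]
    tot <- a$ct[a$target == total_target]
    if (!length(tot)) stop("sample ", s, " lacks the total amplicon", call. = FALSE)
    iso <- a[a$target != total_target, ]
    out[[s]] <- data.frame(sample = s, target = iso$target,
                           fraction = isoform_fraction(iso$ct, tot))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Filter an LFQ table for bait-specific partners
#'
#' A protein is a specific partner when it is detected (LFQ intensity > 0)
#' in at least `min_reps` of the bait replicates, in none of the control
#' replicates, and is identified by at least `min_peptides` razor or unique
#' peptides. The result is sorted by mean bait LFQ intensity, descending.
#'
#' @param table data.frame with columns `protein`, `peptides`, bait
#'   replicate intensity columns (prefix `bait_`) and control columns
#'   (prefix `ctrl_`); 0 (or NA) = not detected.
#' @param min_reps minimum bait replicates with detection.
#' @param min_peptides minimum razor + unique peptide count.
#' @return data.frame of retained rows with `bait_detections` and
#'   `mean_bait_lfq` added.
#' @export
partner_filter <- function(table, min_reps = 2, min_peptides = 2) {
  bait_cols <- grep("^bait_", names(table), value = TRUE)
  ctrl_cols <- grep("^ctrl_", names(table), value = TRUE)
  if (!length(bait_cols) || !length(ctrl_cols))
    stop("table needs bait_* and ctrl_* replicate columns", call. = FALSE)
  bait <- as.matrix(table[, bait_cols, drop = FALSE])
  ctrl <- as.matrix(table[, ctrl_cols, drop = FALSE])
  bait[is.na(bait)] <- 0; ctrl[is.na(ctrl)] <- 0
  det_bait <- rowSums(bait > 0)
  det_ctrl <- rowSums(ctrl > 0)
  keep <- det_bait >= min_reps & det_ctrl == 0 & table$peptides >= min_peptides
  out <- table[keep, , drop = FALSE]
  out$bait_detections <- det_bait[keep]
  out$mean_bait_lfq <- rowMeans(bait[keep, , drop = FALSE])
  out <- out[order(-out$mean_bait_lfq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic LFQ intensity table with known partner labels
#'
#' True partners are detected in at least 2 (of `n_bait_reps`) bait
#' replicates, in no control replicate, and carry >= 2 peptides. Decoys
#' each violate exactly one of the three rules (too few bait detections, a
#' control detection, or a single peptide), drawn cyclically.
#'
#' @param n_true number of true partners.
#' @param n_decoys number of decoys.
#' @param n_bait_reps,n_ctrl_reps replicate counts (defaults 3 and 3).
#' @param seed integer seed.
#' @return list with `table` (data.frame: `protein, peptides, bait_1..,
#'   ctrl_1..`) and `truth` (character vector of true partner ids).
#' @export
gen_lfq_table <- function(n_true = 5, n_decoys = 5, n_bait_reps = 3,
                          n_ctrl_reps = 3, seed = 1L) {
  set.seed(seed)
  n <- n_true + n_decoys
  intensity <- function(k) round(stats::rlnorm(k, meanlog = 21, sdlog = 1))
  rows <- vector("list", n)
  make_row <- function(id, bait_det, ctrl_det, peptides) {
    b <- numeric(n_bait_reps); c_ <- numeric(n_ctrl_reps)
    if (bait_det > 0) b[sample.int(n_bait_reps, bait_det)] <- intensity(bait_det)
    if (ctrl_det > 0) c_[sample.int(n_ctrl_reps, ctrl_det)] <- intensity(ctrl_det)
    as.data.frame(c(list(protein = id, peptides = peptides),
                    stats::setNames(as.list(b), paste0("bait_", seq_len(n_bait_reps))),
                    stats::setNames(as.list(c_), paste0("ctrl_", seq_len(n_ctrl_reps)))))
  }
  truth <- character(0)
  for (i in seq_len(n_true)) {
    id <- sprintf("TRUE%02d", i)
    truth <- c(truth, id)
    rows[[i]] <- make_row(id, bait_det = sample(2:n_bait_reps, 1),
                          ctrl_det = 0, peptides = sample(2:20, 1))
  }
  for (j in seq_len(n_decoys)) {
    id <- sprintf("DECOY%02d", j)
    violation <- (j - 1) %% 3
    rows[[n_true + j]] <- switch(as.character(violation),
      "0" = make_row(id, bait_det = 1, ctrl_det = 0, peptides = sample(2:20, 1)),
      "1" = make_row(id, bait_det = sample(2:n_bait_reps, 1),
                     ctrl_det = sample(seq_len(n_ctrl_reps), 1),
                     peptides = sample(2:20, 1)),
      "2" = make_row(id, bait_det = sample(2:n_bait_reps, 1), ctrl_det = 0,
                     peptides = 1))
  }
  table <- do.call(rbind, rows)
  if (n > 1) table <- table[sample.int(n), , drop = FALSE]
  rownames(table) <- NULL
  list(table = table, truth = truth)
}
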