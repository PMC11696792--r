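#' Delimit overlapping bait fragments along a protein
#'
#' Places `n_fragments` windows of `target_len` residues so that fragment
#' `i` starts at `round((i - 1) * (length - target_len) / (n - 1)) + 1`
#' (1-based, inclusive ends): the first fragment is `(1, target_len)`, the
#' last ends at `length`, and consecutive fragments overlap. When
#' `n_fragments` is omitted, the smallest count giving an overlap of at
#' least 20 residues is used. Alternatively, explicit `delimitations`
#' (a 2-column start/end matrix) are validated and taken verbatim.
#'
#' @param length protein length in residues.
#' @param n_fragments number of fragments (optional).
#' @param target_len fragment length in residues (default 100).
#' @param protein_id identifier stored in the scheme.
#' @param delimitations optional explicit fragments (matrix or data.frame
#'   with columns start, end), overriding the automatic placement.
#' @param min_overlap minimum overlap used to choose `n_fragments`.
#' @return a `fragment_scheme`: data.frame with `fragment, start, end`
#'   plus attributes `protein_id`, `length`.
#' @export
make_fragments <- function(length, n_fragments = NULL, target_len = 100,
                           protein_id = "protein", delimitations = NULL,
                           min_overlap = 20) {
  if (!is.null(delimitations)) {
    dl <- as.data.frame(delimitations)
    names(dl)[1:2] <- c("start", "end")
    if (any(diff(dl$start) <= 0))
      stop("fragment starts must be strictly increasing", call. = FALSE)
    if (any(dl$end < dl$start) || any(dl$start < 1) || any(dl$end > length))
      stop("fragment bounds outside [1, length]", call. = FALSE)
    if (nrow(dl) > 1 && any(dl$start[-1] > dl$end[-nrow(dl)]))
      stop("consecutive fragments must overlap by >= 1 residue", call. = FALSE)
    if (dl$start[1] > 1 || dl$end[nrow(dl)] < length)
      warning("explicit delimitations do not cover [1, ", length, "]")
    out <- data.frame(fragment = seq_len(nrow(dl)), start = as.integer(dl$start),
                      end = as.integer(dl$end))
    attr(out, "protein_id") <- protein_id
    attr(out, "length") <- as.integer(length)
    class(out) <- c("fragment_scheme", "data.frame")
    return(out)
  }
  if (length < target_len) stop("protein shorter than target_len", call. = FALSE)
  if (is.null(n_fragments)) {
    if (length == target_len) n_fragments <- 1L
    else n_fragments <- as.integer(
      ceiling((length - target_len) / (target_len - min_overlap)) + 1L)
  }
  n <- as.integer(n_fragments)
  if (n * target_len < length)
    stop("cannot cover: n_fragments * target_len < length", call. = FALSE)
  if (n == 1) {
    starts <- 1L
  } else {
    starts <- round((seq_len(n) - 1) * (length - target_len) / (n - 1)) + 1L
  }
  out <- data.frame(fragment = seq_len(n), start = as.integer(starts),
                    end = as.integer(starts + target_len - 1L))
  attr(out, "protein_id") <- protein_id
  attr(out, "length") <- as.integer(length)
  class(out) <- c("fragment_scheme", "data.frame")
  out
}

# per-row identity to query and coverage, over query (non-gap) columns;
# identity = matches / aligned (both non-gap) query columns,
# coverage = row's non-gap fraction over query columns
msa_row_stats <- function(query_chars, row_chars) {
  qpos <- query_chars != "-"
  r <- row_chars[qpos]; q <- query_chars[qpos]
  aligned <- r != "-"
  cov <- 100 * mean(aligned)
  id <- if (any(aligned)) 100 * sum(r[aligned] == q[aligned]) / sum(aligned)
  else 0
  c(identity = id, coverage = cov)
}

#' Build a species-tagged MSA object
#'
#' @param sequences character vector of aligned rows (equal lengths, `-`
#'   for gaps); the first row is the query.
#' @param species character vector of species tags (same length).
#' @param ids optional row identifiers.
#' @return a `species_msa`: data.frame with `id, species, sequence,
#'   identity, coverage` (query first; identity/coverage are percentages
#'   relative to the query).
#' @export
species_msa <- function(sequences, species, ids = NULL) {
  if (!length(sequences)) stop("empty MSA: query absent", call. = FALSE)
  w <- nchar(sequences)
  if (length(unique(w)) != 1)
    stop("aligned rows must have equal length", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  qc <- strsplit(sequences[1], "")[[1]]
  st <- t(vapply(strsplit(sequences, ""), msa_row_stats,
                 numeric(2), query_chars = qc))
  out <- data.frame(id = ids, species = species, sequence = sequences,
                    identity = st[, "identity"], coverage = st[, "coverage"],
                    stringsAsFactors = FALSE)
  class(out) <- c("species_msa", "data.frame")
  out
}

#' Read a species-tagged aligned FASTA as a species_msa
#'
#' Headers are parsed for a species tag with `species_regex` (first capture
#' group); the first record is the query.
#'
#' @param path aligned FASTA file.
#' @param species_regex regex with one capture group extracting the species
#'   tag from the header; default takes the token after the last underscore
#'   (UniProt-style `NAME_SPECIES`).
#' @return a `species_msa`.
#' @export
read_species_msa <- function(path, species_regex = ".*_([^_ ]+).*") {
  aa <- Biostrings::readAAStringSet(path)
  species_msa(as.character(aa),
              sub(species_regex, "\\1", names(aa)),
              ids = names(aa))
}

#' Filter an MSA on query identity, coverage and species redundancy
#'
#' Keeps rows with identity-to-query >= `qid` percent and coverage >=
#' `cov` percent; removes exact duplicate rows (with `max_pairwise_id` at
#' its default 100, only 100%-identical rows collapse); keeps only the
#' highest-identity row per species. The query row is always kept.
#'
#' @param msa a [species_msa()].
#' @param qid minimum identity to the query (percent).
#' @param cov minimum coverage of the query (percent).
#' @param max_pairwise_id pairwise identity cap (only 100 is implemented:
#'   exact duplicate removal).
#' @param one_per_species keep a single (best) row per species.
#' @return the filtered `species_msa`.
#' @export
filter_msa <- function(msa, qid = 25, cov = 50, max_pairwise_id = 100,
                       one_per_species = TRUE) {
  if (!nrow(msa)) stop("empty MSA: query absent", call. = FALSE)
  if (max_pairwise_id != 100)
    stop("only max_pairwise_id = 100 (exact duplicate removal) is implemented",
         call. = FALSE)
  query <- msa[1, , drop = FALSE]
  rest <- msa[-1, , drop = FALSE]
  rest <- rest[rest$identity >= qid & rest$coverage >= cov, , drop = FALSE]
  rest <- rest[!duplicated(rest$sequence), , drop = FALSE]
  rest <- rest[rest$sequence != query$sequence, , drop = FALSE]
  if (one_per_species && nrow(rest)) {
    ord <- order(rest$species, -rest$identity)
    rest <- rest[ord, , drop = FALSE]
    rest <- rest[!duplicated(rest$species), , drop = FALSE]
    rest <- rest[order(match(rest$id, msa$id)), , drop = FALSE]
  }
  out <- rbind(query, rest)
  class(out) <- c("species_msa", "data.frame")
  out
}

#' Pair two filtered MSAs by species into a mixed co-alignment
#'
#' Row 1 concatenates the two queries. Each species present in both MSAs
#' contributes one concatenated row; a species present in only one MSA is
#' kept with the partner block padded with gaps. Row order of each input is
#' preserved within its block (paired rows first, then A-only, then
#' B-only). Total width is `widthA + widthB`.
#'
#' @param msa_a,msa_b filtered [species_msa()] objects.
#' @return data.frame with `species, id_a, id_b, sequence`.
#' @export
pair_msas <- function(msa_a, msa_b) {
  if (!nrow(msa_a) || !nrow(msa_b)) stop("empty MSA", call. = FALSE)
  wa <- nchar(msa_a$sequence[1]); wb <- nchar(msa_b$sequence[1])
  gap_a <- strrep("-", wa); gap_b <- strrep("-", wb)
  qa <- msa_a[1, ]; qb <- msa_b[1, ]
  ra <- msa_a[-1, , drop = FALSE]; rb <- msa_b[-1, , drop = FALSE]
  common <- intersect(ra$species, rb$species)
  rows <- list(data.frame(species = paste(qa$species, qb$species, sep = "|"),
                          id_a = qa$id, id_b = qb$id,
                          sequence = paste0(qa$sequence, qb$sequence),
                          stringsAsFactors = FALSE))
  for (sp in ra$species[ra$species %in% common]) {
    a <- ra[ra$species == sp, ][1, ]
    b <- rb[rb$species == sp, ][1, ]
    rows[[length(rows) + 1]] <- data.frame(
      species = sp, id_a = a$id, id_b = b$id,
      sequence = paste0(a$sequence, b$sequence), stringsAsFactors = FALSE)
  }
  for (i in which(!ra$species %in% common))
    rows[[length(rows) + 1]] <- data.frame(
      species = ra$species[i], id_a = ra$id[i], id_b = NA,
      sequence = paste0(ra$sequence[i], gap_b), stringsAsFactors = FALSE)
  for (i in which(!rb$species %in% common))
    rows[[length(rows) + 1]] <- data.frame(
      species = rb$species[i], id_a = NA, id_b = rb$id[i],
      sequence = paste0(gap_a, rb$sequence[i]), stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate per-model predictor scores for one bait/prey pair
#'
#' Scores are on [0, 1] (pLDDT is stored divided by 100). The aggregate
#' confidence of each model is `0.2 * pTM + 0.8 * ipTM`; `avg_iptm` is the
#' arithmetic mean of the models' ipTM and `best_confidence` the maximum
#' per-model confidence.
#'
#' @param models data.frame with columns `plddt, ptm, iptm` (1-5 rows, one
#'   per generated model; pLDDT on the 0-100 scale is rescaled).
#' @param bait,prey identifiers.
#' @return a `score_set`: list with `bait`, `prey`, `models` (with added
#'   `confidence`), `avg_iptm`, `best_confidence`.
#' @export
aggregate_scores <- function(models, bait = "bait", prey = "prey") {
  models <- as.data.frame(models)
  stopifnot(all(c("plddt", "ptm", "iptm") %in% names(models)))
  if (nrow(models) < 1 || nrow(models) > 5)
    stop("expect 1-5 models", call. = FALSE)
  if (any(models$plddt > 1)) models$plddt <- models$plddt / 100
  if (any(models$plddt < 0 | models$plddt > 1 | models$ptm < 0 |
            models$ptm > 1 | models$iptm < 0 | models$iptm > 1))
    stop("scores must lie in [0, 1] (pLDDT in [0, 100])", call. = FALSE)
  models$confidence <- 0.2 * models$ptm + 0.8 * models$iptm
  structure(list(bait = bait, prey = prey, models = models,
                 avg_iptm = mean(models$iptm),
                 best_confidence = max(models$confidence)),
            class = "score_set")
}

#' Rank fragment-screen candidates above a confidence threshold
#'
#' Retains score sets whose selector column is strictly above `threshold`
#' (0.65 by default) and sorts them by `rank_by` descending; ties are broken
#' by `best_confidence`, then lexically by bait and prey id.
#'
#' @param score_sets list of [aggregate_scores()] results.
#' @param threshold strict lower bound on the selector.
#' @param rank_by ranking column: `"avg_iptm"` (default) or
#'   `"best_confidence"`.
#' @param select_by column compared against the threshold (default
#'   `"best_confidence"`).
#' @return data.frame `bait, prey, avg_iptm, best_confidence`, ranked.
#' @export
screen_candidates <- function(score_sets, threshold = 0.65,
                              rank_by = c("avg_iptm", "best_confidence"),
                              select_by = c("best_confidence", "avg_iptm")) {
  rank_by <- match.arg(rank_by); select_by <- match.arg(select_by)
  df <- do.call(rbind, lapply(score_sets, function(s)
    data.frame(bait = s$bait, prey = s$prey, avg_iptm = s$avg_iptm,
               best_confidence = s$best_confidence, stringsAsFactors = FALSE)))
  if (is.null(df)) return(data.frame(bait = character(), prey = character(),
                                     avg_iptm = numeric(),
                                     best_confidence = numeric()))
  df <- df[df[[select_by]] > threshold, , drop = FALSE]
  df <- df[order(-df[[rank_by]], -df$best_confidence, df$bait, df$prey), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Mock structure-prediction backend returning scores from a fixture table
#'
#' Stands in for an external predictor in tests and examples: scores for
#' each (bait, prey) pair are looked up in a user-supplied table.
#'
#' @param score_table data.frame with columns `bait, prey, model, plddt,
#'   ptm, iptm`.
#' @return a predictor function `(bait, prey) -> score_set`.
#' @export
mock_predictor <- function(score_table) {
  force(score_table)
  function(bait, prey) {
    rows <- score_table[score_table$bait == bait & score_table$prey == prey, ]
    if (!nrow(rows)) stop("no scores for pair ", bait, " / ", prey, call. = FALSE)
    aggregate_scores(rows[, c("plddt", "ptm", "iptm")], bait = bait, prey = prey)
  }
}

#' Run a fragment screen through a predictor backend
#'
#' @param baits character vector of bait fragment ids.
#' @param preys character vector of prey domain ids.
#' @param predictor function `(bait, prey) -> score_set`, e.g.
#'   [mock_predictor()].
#' @param threshold,rank_by,select_by passed to [screen_candidates()].
#' @return ranked candidate table.
#' @export
run_screen <- function(baits, preys, predictor, threshold = 0.65,
                       rank_by = "avg_iptm", select_by = "best_confidence") {
  sets <- list()
  for (b in baits) for (p in preys)
    sets[[length(sets) + 1]] <- predictor(b, p)
  screen_candidates(sets, threshold = threshold, rank_by = rank_by,
                    select_by = select_by)
}
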