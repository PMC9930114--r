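#' Binarize a chain into hydrophobic/hydrophilic labels
#'
#' Applies [classify_monomer()] position-by-position: a monomer is
#' `"phobic"` when its HLB is strictly below the system threshold,
#' `"philic"` otherwise. The source monomer indices are retained as an
#' attribute so the motif search can still see chemical identity.
#'
#' @param chain integer vector of monomer indices.
#' @param system a [monomer_system()].
#' @param threshold HLB cutoff; defaults to the system's `hlb_threshold`.
#' @return Character vector of `"phobic"`/`"philic"` labels with attribute
#'   `"indices"` (the source chain).
#' @export
binarize_chain <- function(chain, system, threshold = system$hlb_threshold) {
  if (any(chain < 1 | chain > length(system$symbols)))
    stop("chain contains monomer indices outside the system")
  labels <- classify_monomer(system$hlb[chain], threshold)
  attr(labels, "indices") <- chain
  labels
}

#' Run lengths per class
#'
#' Scans a labeled sequence left to right (alpha to omega) and returns the
#' lengths of its maximal runs, grouped by class. A segment is a contiguous
#' run of identically labeled positions.
#'
#' @param labels character (or factor) vector of class labels, e.g. the
#'   output of [binarize_chain()].
#' @return Named list: for each class observed (and always for `"phobic"`
#'   and `"philic"`), the integer vector of its run lengths in order of
#'   appearance.
#' @examples
#' run_segments(c("phobic", "phobic", "philic", "phobic"))
#' @export
run_segments <- function(labels) {
  labels <- as.character(labels)
  classes <- union(c("phobic", "philic"), unique(labels))
  if (!length(labels))
    return(setNames(lapply(classes, function(z) integer()), classes))
  r <- rle(labels)
  setNames(lapply(classes, function(z) r$lengths[r$values == z]), classes)
}

#' Segment length distribution of a batch
#'
#' Counts maximal hydrophobic (or hydrophilic) runs of each length across
#' all chains of a batch. At the sequence level the counts are averaged per
#' chain (count / NC: the mean number of segments of that length a chain
#' carries); at the batch level they are summed. The two levels differ by
#' the constant factor NC.
#'
#' @param batch a nonempty `rhp_batch`.
#' @param class `"phobic"` or `"philic"`.
#' @param level `"sequence"` (average frequency per chain) or `"batch"`
#'   (summed counts).
#' @param threshold HLB cutoff; defaults to the system threshold.
#' @return A data.frame with columns `level`, `class`, `length`, `value`,
#'   sorted by length. Empty (zero rows) when no run of the class exists.
#' @export
segment_distribution <- function(batch, class = c("phobic", "philic"),
                                 level = c("sequence", "batch"),
                                 threshold = batch$system$hlb_threshold) {
  stopifnot(inherits(batch, "rhp_batch"))
  if (!length(batch$chains)) stop("cannot analyze an empty batch")
  class <- match.arg(class)
  level <- match.arg(level)
  runs <- unlist(lapply(batch$chains, function(ch)
    run_segments(binarize_chain(ch, batch$system, threshold))[[class]]),
    use.names = FALSE)
  if (!length(runs))
    return(data.frame(level = character(), class = character(),
                      length = integer(), value = numeric()))
  tab <- table(runs)
  value <- as.numeric(tab)
  if (level == "sequence") value <- value / length(batch$chains)
  data.frame(level = level, class = class,
             length = as.integer(names(tab)), value = value)
}

#' @rdname segment_distribution
#' @export
sequence_level_distribution <- function(batch, class = "phobic",
                                        threshold = batch$system$hlb_threshold)
  segment_distribution(batch, class, "sequence", threshold)

#' @rdname segment_distribution
#' @export
batch_level_distribution <- function(batch, class = "phobic",
                                     threshold = batch$system$hlb_threshold)
  segment_distribution(batch, class, "batch", threshold)

#' Search for hydrophobic segments with one embedded marker
#'
#' Finds "specific segments": maximal runs over the extended alphabet
#' {hydrophobic monomers} U {marker} that contain exactly one marker unit,
#' with the marker at least `end_gap` non-marker monomers away from both
#' ends of the run. This is the motif associated with membrane-protein-like
#' proton transport in RHPs — a hydrophobic stretch carrying a single
#' embedded hydrophilic ether unit (OEGMA by default). Runs containing two
#' or more markers yield no match.
#'
#' @param batch a nonempty `rhp_batch`.
#' @param marker monomer symbol of the embedded unit (default `"OEGMA"`).
#' @param end_gap minimum number of non-marker monomers between the marker
#'   and each run end (default 2).
#' @return A list with
#'   \item{matches}{data.frame `chain`, `start`, `end` (0-based half-open
#'     within the chain), `marker_pos` (0-based), `length`;}
#'   \item{distribution}{sequence-level data.frame (`level`, `class =
#'     "motif"`, `length`, `value = count / NC`);}
#'   \item{batch_distribution}{batch-level summed counts;}
#'   \item{length_density}{Gaussian kernel density over match lengths
#'     (`NULL` when fewer than 2 distinct lengths).}
#' @examples
#' sys <- default_system()
#' b <- generate_fixture("handcrafted",
#'        sequences = list(c("MMA", "MMA", "OEGMA", "MMA", "MMA")),
#'        system = sys)
#' find_specific_segments(b)$matches
#' @export
find_specific_segments <- function(batch, marker = "OEGMA", end_gap = 2) {
  stopifnot(inherits(batch, "rhp_batch"))
  if (!length(batch$chains)) stop("cannot analyze an empty batch")
  sys <- batch$system
  mi <- monomer_index(sys, marker)
  phobic <- classify_monomer(sys$hlb, sys$hlb_threshold) == "phobic"

  match_one <- function(ch, id) {
    in_run <- phobic[ch] | ch == mi
    r <- rle(in_run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hits <- list()
    for (q in which(r$values)) {
      p1 <- starts[q]; p2 <- ends[q]
      mk <- which(ch[p1:p2] == mi)
      if (length(mk) != 1) next
      pos <- mk - 1L                       # 0-based within run
      L <- p2 - p1 + 1L
      if (pos >= end_gap && (L - 1L - pos) >= end_gap)
        hits[[length(hits) + 1]] <- data.frame(
          chain = id, start = p1 - 1L, end = p2,
          marker_pos = p1 - 1L + pos, length = L)
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }

  matches <- do.call(rbind, Map(match_one, batch$chains,
                                seq_along(batch$chains)))
  if (is.null(matches))
    matches <- data.frame(chain = integer(), start = integer(),
                          end = integer(), marker_pos = integer(),
                          length = integer())
  rownames(matches) <- NULL
  nc <- length(batch$chains)
  if (nrow(matches)) {
    tab <- table(matches$length)
    seq_df <- data.frame(level = "sequence", class = "motif",
                         length = as.integer(names(tab)),
                         value = as.numeric(tab) / nc)
    bat_df <- data.frame(level = "batch", class = "motif",
                         length = as.integer(names(tab)),
                         value = as.numeric(tab))
  } else {
    seq_df <- bat_df <- data.frame(level = character(), class = character(),
                                   length = integer(), value = numeric())
  }
  dens <- if (length(unique(matches$length)) >= 2)
    density(matches$length) else NULL
  list(matches = matches, distribution = seq_df,
       batch_distribution = bat_df, length_density = dens)
}
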