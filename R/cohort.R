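#' Consequence vocabularies
#'
#' Variant consequence terms recognized by [classify_consequence()], grouped
#' by modality. Protein-disrupting terms count as deleterious; synonymous,
#' splice and UTR terms as non-deleterious.
#'
#' @format Character vectors of consequence terms.
#' @name consequence_terms
NULL

DELETERIOUS_TERMS <- c(
  "Inframe", "Frameshift", "Missense", "Start Lost", "Stop Gained", "Stop Lost"
)
NON_DELETERIOUS_TERMS <- c(
  "Synonimous", "Splice", "UTR 5 prime", "UTR 3 prime"
)

#' Specify a synthetic pan-cancer cohort
#'
#' Defines the generative model for a synthetic cohort of tumor samples with
#' nested tumor type / subtype labels and two somatic-mutation modalities
#' (deleterious, non-deleterious). Each subtype owns a disjoint set of marker
#' genes; in the modality (or modalities) carrying signal, a marker gene of a
#' sample's own subtype mutates at `marker_rate`, every other (sample, gene,
#' modality) cell mutates at `background_rate`. A fraction of subtypes is
#' designated pure noise: these have no subtype-level marker set — each
#' noise sample elevates its own random passenger genes instead, matching
#' the mutation burden of signal subtypes while offering no consistent
#' pattern — giving downstream classifiers a built-in negative control.
#'
#' Counts per cell are the sum of two Bernoulli trials, so a cell takes the
#' value 0, 1 or 2 and the expected count is `2 * rate`. This keeps the
#' "number of mutations per gene" semantics of real count matrices while
#' keeping all marginal expectations analytic.
#'
#' @param n_types Number of tumor types (primary sites).
#' @param subtypes_per_type Integer vector (recycled to `n_types`) giving the
#'   number of subtypes nested under each type.
#' @param samples_per_subtype Samples simulated per subtype (recycled to the
#'   total number of subtypes).
#' @param n_genes Size of the gene universe.
#' @param background_rate Per-trial mutation probability for background cells.
#' @param marker_rate Per-trial mutation probability for a sample's own marker
#'   genes in the signal modality; must exceed `background_rate` when any
#'   marker enrichment exists.
#' @param marker_genes_per_subtype Number of marker genes owned by each
#'   signal subtype; marker sets of distinct subtypes are disjoint.
#' @param signal_modality One of `"deleterious_only"`, `"non_deleterious_only"`,
#'   `"both"`: where marker enrichment is placed.
#' @param noise_subtype_fraction Fraction of subtypes (rounded to a count)
#'   that get no marker enrichment at all.
#' @param seed Integer seed governing all draws; per-subtype sub-streams are
#'   derived from it deterministically.
#'
#' @return An object of class `"cohort_spec"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_types = 14,
                        subtypes_per_type = 3,
                        samples_per_subtype = 60,
                        n_genes = 1000,
                        background_rate = 0.01,
                        marker_rate = 0.3,
                        marker_genes_per_subtype = 15,
                        signal_modality = c("both", "deleterious_only",
                                            "non_deleterious_only"),
                        noise_subtype_fraction = 0.1,
                        seed = 1L) {
  signal_modality <- match.arg(signal_modality)
  spec <- list(
    n_types = as.integer(n_types),
    subtypes_per_type = as.integer(rep_len(subtypes_per_type, n_types)),
    samples_per_subtype = samples_per_subtype,
    n_genes = as.integer(n_genes),
    background_rate = background_rate,
    marker_rate = marker_rate,
    marker_genes_per_subtype = as.integer(marker_genes_per_subtype),
    signal_modality = signal_modality,
    noise_subtype_fraction = noise_subtype_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_spec field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (length(spec$n_types) != 1L || is.na(spec$n_types) || spec$n_types < 1L)
    stop_field("n_types", "must be a positive integer")
  if (any(is.na(spec$subtypes_per_type)) || any(spec$subtypes_per_type < 1L))
    stop_field("subtypes_per_type", "all counts must be >= 1")
  n_subtypes <- sum(spec$subtypes_per_type)
  sps <- rep_len(spec$samples_per_subtype, n_subtypes)
  if (any(is.na(sps)) || any(sps < 1))
    stop_field("samples_per_subtype", "all counts must be >= 1")
  if (spec$n_genes < 1L)
    stop_field("n_genes", "must be >= 1")
  for (f in c("background_rate", "marker_rate")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a probability in [0, 1]")
  }
  has_markers <- spec$marker_genes_per_subtype > 0L &&
    n_signal_subtypes(spec) > 0L && spec$marker_rate > 0
  if (has_markers && spec$marker_rate <= spec$background_rate)
    stop_field("marker_rate",
               "must exceed background_rate when marker enrichment exists")
  if (spec$marker_genes_per_subtype < 0L)
    stop_field("marker_genes_per_subtype", "must be >= 0")
  needed <- spec$marker_genes_per_subtype * n_signal_subtypes(spec)
  if (needed > spec$n_genes)
    stop_field("marker_genes_per_subtype",
               sprintf("disjoint marker sets need %d genes but n_genes = %d",
                       needed, spec$n_genes))
  if (spec$noise_subtype_fraction < 0 || spec$noise_subtype_fraction > 1)
    stop_field("noise_subtype_fraction", "must lie in [0, 1]")
  invisible(spec)
}

n_noise_subtypes <- function(spec) {
  n_subtypes <- sum(spec$subtypes_per_type)
  round(spec$noise_subtype_fraction * n_subtypes)
}

n_signal_subtypes <- function(spec) {
  sum(spec$subtypes_per_type) - n_noise_subtypes(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  n_subtypes <- sum(x$subtypes_per_type)
  sps <- rep_len(x$samples_per_subtype, n_subtypes)
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d tumor types / %d subtypes (%d noise), %d samples, %d genes\n",
              x$n_types, n_subtypes, n_noise_subtypes(x), sum(sps), x$n_genes))
  cat(sprintf("  background rate %.4g, marker rate %.4g (%d markers/subtype, %s)\n",
              x$background_rate, x$marker_rate, x$marker_genes_per_subtype,
              x$signal_modality))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate a synthetic pan-cancer cohort
#'
#' Draws per-cell mutation counts under the generative model described in
#' [cohort_spec()] and expands them into annotated mutation records, one row
#' per mutation event, with consequence terms sampled from the modality's
#' vocabulary. Identical seeds give byte-identical output.
#'
#' @param spec A [cohort_spec()] object.
#' @return A list of class `"cohort"` with elements:
#'   \describe{
#'     \item{records}{data.frame with columns `sample_id`, `gene`,
#'       `tumor_type`, `tumor_subtype`, `consequence` (one row per mutation).}
#'     \item{truth}{named list mapping each subtype to its marker gene set
#'       (character(0) for noise subtypes), plus attributes carrying the
#'       per-sample label tables.}
#'     \item{samples}{data.frame of all simulated samples with their labels
#'       (includes samples that happen to carry zero mutations).}
#'   }
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_subtypes <- sum(spec$subtypes_per_type)
  sps <- rep_len(as.integer(spec$samples_per_subtype), n_subtypes)

  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  type_of_subtype <- rep(seq_len(spec$n_types), spec$subtypes_per_type)
  type_names <- sprintf("T%02d", seq_len(spec$n_types))
  subtype_names <- character(n_subtypes)
  idx_within <- unlist(lapply(spec$subtypes_per_type, seq_len))
  subtype_names <- sprintf("%s.S%d", type_names[type_of_subtype], idx_within)

  ## global stream: noise designation, marker assignment, per-subtype seeds
  set.seed(spec$seed)
  n_noise <- n_noise_subtypes(spec)
  noise_subtypes <- if (n_noise > 0L)
    sort(sample.int(n_subtypes, n_noise)) else integer(0)
  signal_subtypes <- setdiff(seq_len(n_subtypes), noise_subtypes)

  marker_pool <- sample.int(spec$n_genes)  # random disjoint blocks
  truth <- stats::setNames(vector("list", n_subtypes), subtype_names)
  pos <- 0L
  for (s in signal_subtypes) {
    take <- seq_len(spec$marker_genes_per_subtype) + pos
    truth[[s]] <- sort(genes[marker_pool[take]])
    pos <- pos + spec$marker_genes_per_subtype
  }
  for (s in noise_subtypes) truth[[s]] <- character(0)
  subtype_seeds <- sample.int(.Machine$integer.max, n_subtypes)

  active_de <- spec$signal_modality %in% c("both", "deleterious_only")
  active_nd <- spec$signal_modality %in% c("both", "non_deleterious_only")

  rec_list <- vector("list", n_subtypes)
  sample_tabs <- vector("list", n_subtypes)
  for (s in seq_len(n_subtypes)) {
    set.seed(subtype_seeds[s])
    n_s <- sps[s]
    ids <- sprintf("%s.%04d", subtype_names[s], seq_len(n_s))
    sample_tabs[[s]] <- data.frame(
      sample_id = ids,
      tumor_type = type_names[type_of_subtype[s]],
      tumor_subtype = subtype_names[s],
      stringsAsFactors = FALSE
    )
    marker_idx <- match(truth[[s]], genes)
    is_noise <- s %in% noise_subtypes
    ## noise subtypes: no consistent marker set, but the same expected
    ## burden -- each sample elevates its own random draw from the other
    ## subtypes' marker genes (assorted drivers, no subtype-level pattern),
    ## so the subtype is identifiable neither by burden nor by any gene set
    passenger_pool <- match(unlist(truth), genes)
    if (length(passenger_pool) < spec$marker_genes_per_subtype)
      passenger_pool <- seq_len(spec$n_genes)
    sub_recs <- list()
    for (modality in c("de", "nd")) {
      p <- matrix(spec$background_rate, nrow = n_s, ncol = spec$n_genes)
      enriched <- (modality == "de" && active_de) ||
        (modality == "nd" && active_nd)
      if (enriched && length(marker_idx))
        p[, marker_idx] <- spec$marker_rate
      if (enriched && is_noise && spec$marker_genes_per_subtype > 0L &&
          length(passenger_pool) >= spec$marker_genes_per_subtype) {
        for (i in seq_len(n_s)) {
          pg <- sample(passenger_pool, spec$marker_genes_per_subtype)
          p[i, pg] <- spec$marker_rate
        }
      }
      counts <- matrix(
        stats::rbinom(n_s * spec$n_genes, size = 2L, prob = p),
        nrow = n_s
      )
      nz <- which(counts > 0L, arr.ind = TRUE)
      if (nrow(nz) == 0L) next
      reps <- counts[nz]
      terms <- if (modality == "de") DELETERIOUS_TERMS else NON_DELETERIOUS_TERMS
      n_events <- sum(reps)
      sub_recs[[modality]] <- data.frame(
        sample_id = rep(ids[nz[, 1L]], reps),
        gene = rep(genes[nz[, 2L]], reps),
        tumor_type = type_names[type_of_subtype[s]],
        tumor_subtype = subtype_names[s],
        consequence = sample(terms, n_events, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    rec_list[[s]] <- do.call(rbind, sub_recs)
  }
  rec_list <- rec_list[!vapply(rec_list, is.null, TRUE)]
  records <- if (length(rec_list))
    do.call(rbind, c(rec_list, list(make.row.names = FALSE))) else NULL
  if (is.null(records))
    records <- data.frame(sample_id = character(0), gene = character(0),
                          tumor_type = character(0),
                          tumor_subtype = character(0),
                          consequence = character(0),
                          stringsAsFactors = FALSE)
  ## deterministic canonical order
  records <- records[order(records$sample_id, records$gene,
                           records$consequence), , drop = FALSE]
  rownames(records) <- NULL
  samples <- do.call(rbind, c(sample_tabs, list(make.row.names = FALSE)))

  structure(
    list(records = records, truth = truth, samples = samples,
         noise_subtypes = subtype_names[noise_subtypes], spec = spec),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d mutation records, %d samples, %d subtypes (%d noise)\n",
              nrow(x$records), nrow(x$samples), length(x$truth),
              length(x$noise_subtypes)))
  invisible(x)
}

#' Write / read MAF-like mutation records
#'
#' `write_maf()` serializes mutation records to the tab-separated format
#' consumed by [read_maf()] and [build_count_matrices()]: one row per
#' mutation with a header line and columns `sample_id`, `gene`, `tumor_type`,
#' `tumor_subtype`, `consequence`.
#'
#' @param records A mutation-record data.frame (e.g. `simulate_cohort(..)$records`).
#' @param path Output (input) file path.
#' @param columns Named character vector remapping the five canonical column
#'   names to the names used in the file, for `read_maf()`.
#' @return `write_maf()` returns `path` invisibly; `read_maf()` returns a
#'   records data.frame with canonical column names.
#' @export
write_maf <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path, columns = c(sample_id = "sample_id",
                                       gene = "gene",
                                       tumor_type = "tumor_type",
                                       tumor_subtype = "tumor_subtype",
                                       consequence = "consequence")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop("MAF-like file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- df[, unname(columns)]
  names(out) <- names(columns)
  out
}

#' Serialize the subtype marker-gene truth map
#'
#' @param cohort A `"cohort"` object from [simulate_cohort()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  jsonlite::write_json(cohort$truth, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
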