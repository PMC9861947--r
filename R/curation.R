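# recognized concentration units, as factors to nM
UNIT_TO_NM <- c(nM = 1, uM = 1e3, `µM` = 1e3, mM = 1e6, M = 1e9)

POTENCY_ENDPOINTS <- c("IC50", "GI50", "Ki", "Kact")

#' Convert a concentration to nanomolar
#'
#' Molar units are converted by exact powers of ten; `%` (inhibition) and
#' the unitless negative log scale pass through unchanged. Unknown units are
#' an error: no molar-mass-based conversion is attempted.
#'
#' @param value numeric vector.
#' @param units character vector of units (`nM`, `uM`/`µM`, `mM`, `M`).
#' @return Numeric vector in nM.
#' @export
convert_to_nM <- function(value, units) {
  units <- trimws(units)
  f <- UNIT_TO_NM[units]
  if (anyNA(f))
    stop("unknown concentration units: ",
         paste(unique(units[is.na(f)]), collapse = ", "), call. = FALSE)
  unname(value * f)
}

#' Label activity records active / inactive / dropped
#'
#' Implements the qualitative labeling rules used to build cytotoxicity and
#' mechanism-of-action training sets:
#' \describe{
#'   \item{`chembl_pubchem`}{potency endpoints (IC50, GI50, Ki, Kact) are
#'     converted to nM and a compound is active iff the value is strictly
#'     below 10,000 nM; percent inhibition is active iff strictly above 50.
#'     Everything tested but not active is inactive.}
#'   \item{`nci60`}{records with a non-empty failure reason are dropped;
#'     the endpoint is the negative log10 GI50 (molar scale) and a compound
#'     is active iff the value is at or above 9, 8 or 7 for the 1 nM, 10 nM
#'     and 100 nM potency thresholds respectively. Values outside the
#'     sanity window [0, 15] are dropped with a warning.}
#' }
#'
#' @param records data.frame with columns `compound_id`, `activity_id`,
#'   `endpoint` (`IC50`, `GI50`, `Ki`, `Kact`, `PCT_INHIBITION`,
#'   `NEG_LOG_GI50`), `value`, `units`, and optionally `failure_reason`.
#' @param ruleset `"chembl_pubchem"` or `"nci60"`.
#' @param nci60_threshold `"1nM"`, `"10nM"` or `"100nM"`; required iff
#'   `ruleset = "nci60"`.
#' @return Character vector (`"active"`, `"inactive"`, `"dropped"`), one
#'   per record. Labeling is a pure function of each record: row order
#'   never matters.
#' @examples
#' recs <- data.frame(compound_id = "c1", activity_id = "MCF7",
#'                    endpoint = "IC50", value = 5, units = "uM")
#' label_records(recs, "chembl_pubchem")   # 5 uM = 5000 nM -> active
#' @export
label_records <- function(records, ruleset = c("chembl_pubchem", "nci60"),
                          nci60_threshold = NULL) {
  ruleset <- match.arg(ruleset)
  n <- nrow(records)
  if (is.null(records$failure_reason)) records$failure_reason <- ""
  records$failure_reason[is.na(records$failure_reason)] <- ""
  if (any(!is.finite(records$value)))
    stop("non-finite activity values", call. = FALSE)
  lab <- character(n)
  if (ruleset == "chembl_pubchem") {
    if (!is.null(nci60_threshold))
      stop("nci60_threshold applies only to ruleset 'nci60'", call. = FALSE)
    for (i in seq_len(n)) {
      ep <- records$endpoint[i]
      if (ep %in% POTENCY_ENDPOINTS) {
        nm <- convert_to_nM(records$value[i], records$units[i])
        lab[i] <- if (nm < 10000) "active" else "inactive"
      } else if (ep == "PCT_INHIBITION") {
        lab[i] <- if (records$value[i] > 50) "active" else "inactive"
      } else {
        stop("endpoint '", ep, "' not valid under ruleset 'chembl_pubchem'",
             call. = FALSE)
      }
    }
  } else {
    if (is.null(nci60_threshold))
      stop("ruleset 'nci60' requires nci60_threshold", call. = FALSE)
    nci60_threshold <- match.arg(nci60_threshold, c("1nM", "10nM", "100nM"))
    cut <- c(`1nM` = 9, `10nM` = 8, `100nM` = 7)[[nci60_threshold]]
    for (i in seq_len(n)) {
      if (nzchar(records$failure_reason[i])) { lab[i] <- "dropped"; next }
      if (records$endpoint[i] != "NEG_LOG_GI50")
        stop("ruleset 'nci60' expects endpoint NEG_LOG_GI50", call. = FALSE)
      v <- records$value[i]
      if (v < 0 || v > 15) {
        warning(sprintf("-log10 GI50 = %g outside sanity window [0, 15]; %s",
                        v, "record dropped"), call. = FALSE)
        lab[i] <- "dropped"
        next
      }
      lab[i] <- if (v >= cut) "active" else "inactive"
    }
  }
  lab
}

#' @rdname label_records
#' @param rec a single-record list or one-row data.frame.
#' @export
label_record <- function(rec, ruleset = c("chembl_pubchem", "nci60"),
                         nci60_threshold = NULL) {
  label_records(as.data.frame(rec, stringsAsFactors = FALSE), ruleset,
                nci60_threshold)
}

#' Aggregate replicate NCI60 growth-inhibition measurements
#'
#' Replicate negative log10 GI50 values for one compound x cell-line pair
#' are collapsed to their median (robust to the screening campaign's
#' occasional outlier replicate; switchable to the mean).
#'
#' @param values numeric vector of replicate -log10 GI50 values (at least
#'   one).
#' @param method `"median"` (default) or `"mean"`.
#' @return Single aggregated value.
#' @export
aggregate_gi50 <- function(values, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!length(values)) stop("no replicate values to aggregate", call. = FALSE)
  if (method == "median") stats::median(values) else mean(values)
}

#' Standardize an activity (cell-line or target) name
#'
#' Lookup keys are case-folded with whitespace and punctuation stripped, so
#' `"MCF-7"`, `"mcf7"` and `" MCF 7 "` hit the same synonym entry. Unmapped
#' names pass through with outer whitespace trimmed and inner runs
#' collapsed. The same mechanism serves as the exact-match key merge for
#' mechanism-of-action target identifiers.
#'
#' @param raw character vector of raw names.
#' @param synonyms named character vector: names are raw synonyms (any
#'   case/punctuation), values the standardized names. `NULL` for none.
#' @return Character vector of standardized names.
#' @examples
#' normalize_activity_name("mcf-7", c(MCF7 = "MCF7"))  # "MCF7"
#' normalize_activity_name(" A549 ")                    # "A549"
#' @export
normalize_activity_name <- function(raw, synonyms = NULL) {
  squeeze <- function(x) gsub("\\s+", " ", trimws(x))
  key <- function(x) tolower(gsub("[^[:alnum:]]", "", x))
  out <- squeeze(raw)
  if (length(synonyms)) {
    lookup <- as.character(synonyms)
    names(lookup) <- key(names(synonyms))
    hit <- lookup[key(out)]
    out[!is.na(hit)] <- hit[!is.na(hit)]
  }
  unname(out)
}

#' Read a two-column synonym / target-key table
#'
#' @param path delimited file (comma or tab, autodetected) whose first
#'   column is the raw name and second the standardized name. A header
#'   line is required.
#' @return Named character vector suitable for [normalize_activity_name()].
#' @export
read_synonym_table <- function(path) {
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L)
    stop("synonym table needs two columns (raw, standardized)", call. = FALSE)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

# comma/tab autodetection on the header line
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' Read a raw activity table
#'
#' Delimited text (comma or tab autodetected), header required. Expected
#' columns: `compound_id`, `activity_id`, `endpoint`, `value`, `units`;
#' optional: `structure` (SMILES), `failure_reason`.
#'
#' @param path file path.
#' @return data.frame of activity records.
#' @export
read_activity_table <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("compound_id", "activity_id", "endpoint", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("activity table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$units)) tab$units <- ""
  tab$value <- as.numeric(tab$value)
  tab
}

#' Build per-activity binary labeled sets
#'
#' Records are labeled by [label_records()]; under the `nci60` ruleset,
#' failure-reason and sanity-window drops are applied first and surviving
#' replicates per compound x cell line are collapsed with [aggregate_gi50()]
#' before thresholding. Per-compound conflicts within one activity resolve
#' active-wins: any qualifying active measurement makes the compound active
#' (inactivity is only ever the absence of activity). Activities keep a
#' labeled set only with at least `min_actives` actives and at least one
#' inactive.
#'
#' @inheritParams label_records
#' @param min_actives minimum actives per retained activity (default 3: a
#'   per-activity Bayesian model is meaningless below that).
#' @param synonyms optional synonym map applied to `activity_id` via
#'   [normalize_activity_name()].
#' @param aggregate replicate aggregation method for `nci60`
#'   (`"median"`/`"mean"`).
#' @return List of `labeled_set` objects (fields `activity_id`,
#'   `compound_id`, `label`), with attribute `summary`: a data.frame of
#'   per-activity record accounting (`n_active`, `n_inactive`, `n_dropped`
#'   sum to the record count per activity) plus compound-level class sizes
#'   and a `retained` flag.
#' @export
build_labeled_sets <- function(records,
                               ruleset = c("chembl_pubchem", "nci60"),
                               nci60_threshold = NULL, min_actives = 3L,
                               synonyms = NULL,
                               aggregate = c("median", "mean")) {
  ruleset <- match.arg(ruleset)
  aggregate <- match.arg(aggregate)
  records$activity_id <- normalize_activity_name(records$activity_id,
                                                 synonyms)
  if (ruleset == "nci60") {
    rec_lab <- label_records(records, "nci60", nci60_threshold)
    kept <- records[rec_lab != "dropped", , drop = FALSE]
    agg <- stats::aggregate(
      kept$value, by = list(compound_id = kept$compound_id,
                            activity_id = kept$activity_id),
      FUN = aggregate_gi50, method = aggregate)
    names(agg)[3L] <- "value"
    agg$endpoint <- "NEG_LOG_GI50"
    agg$units <- ""
    lab <- label_records(agg, "nci60", nci60_threshold)
    labeled <- data.frame(compound_id = agg$compound_id,
                          activity_id = agg$activity_id, label = lab,
                          stringsAsFactors = FALSE)
  } else {
    rec_lab <- label_records(records, "chembl_pubchem")
    labeled <- data.frame(compound_id = records$compound_id,
                          activity_id = records$activity_id, label = rec_lab,
                          stringsAsFactors = FALSE)
  }
  rec_counts <- table(records$activity_id,
                      factor(rec_lab,
                             levels = c("active", "inactive", "dropped")))

  sets <- list()
  acts <- sort(unique(labeled$activity_id))
  summary_rows <- vector("list", length(acts))
  for (k in seq_along(acts)) {
    a <- acts[k]
    sub <- labeled[labeled$activity_id == a, , drop = FALSE]
    # active-wins conflict resolution, order-independent
    is_active <- tapply(sub$label == "active", sub$compound_id, any)
    ids <- names(is_active)
    n_act <- sum(is_active)
    n_inact <- sum(!is_active)
    retained <- n_act >= min_actives && n_inact >= 1L
    if (retained)
      sets[[a]] <- labeled_set(a, ids,
                               ifelse(is_active, "active", "inactive"))
    summary_rows[[k]] <- data.frame(
      activity_id = a,
      n_records_active = rec_counts[a, "active"],
      n_records_inactive = rec_counts[a, "inactive"],
      n_records_dropped = rec_counts[a, "dropped"],
      n_active = n_act, n_inactive = n_inact,
      n_dropped = unname(rec_counts[a, "dropped"]),
      retained = retained, stringsAsFactors = FALSE)
  }
  if (!length(sets))
    stop("no activity survived curation (min_actives = ", min_actives,
         "); see the summary for per-activity counts", call. = FALSE)
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  for (r in seq_len(nrow(summary)))
    message(sprintf(
      "curation %s: %d active / %d inactive compounds, %d records dropped%s",
      summary$activity_id[r], summary$n_active[r], summary$n_inactive[r],
      summary$n_dropped[r],
      if (summary$retained[r]) "" else " [activity omitted]"))
  attr(sets, "summary") <- summary
  sets
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("labeled_set '%s': %d active, %d inactive\n", x$activity_id,
              sum(x$label == "active"), sum(x$label == "inactive")))
  invisible(x)
}

#' Construct a labeled set directly
#'
#' @param activity_id activity name.
#' @param compound_id character vector of compound ids (unique).
#' @param label parallel vector of `"active"` / `"inactive"`.
#' @return A `labeled_set`.
#' @export
labeled_set <- function(activity_id, compound_id, label) {
  stopifnot(length(compound_id) == length(label),
            !anyDuplicated(compound_id),
            all(label %in% c("active", "inactive")))
  structure(list(activity_id = as.character(activity_id),
                 compound_id = unname(as.character(compound_id)),
                 label = unname(as.character(label))),
            class = "labeled_set")
}
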