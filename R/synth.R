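#' Configuration for the synthetic descriptor generator
#'
#' The generator emulates a curated binary training set at the descriptor
#' level: each compound's descriptor set is drawn by independent inclusion
#' of vocabulary items, with a small block of "enriched" items included
#' with higher probability in actives than in inactives — a planted,
#' tunable structure-activity signal whose strength is known by
#' construction. Defaults describe a strongly separable set of 300 actives
#' and 1200 inactives over a 500-item vocabulary with 10 enriched items at
#' inclusion probabilities 0.9 (actives) vs 0.1 (inactives) over a 0.05
#' background.
#'
#' @param n_active,n_inactive class sizes (both >= 1).
#' @param vocab_size vocabulary size.
#' @param n_enriched number of signal-carrying items (<= vocab_size).
#' @param p_enriched_in_active,p_enriched_in_inactive inclusion
#'   probabilities of enriched items per class; a planted signal requires
#'   the former to exceed the latter (equality gives a null dataset, which
#'   is permitted).
#' @param p_background inclusion probability of every other item.
#' @param seed integer seed; all randomness flows through it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_active = 300L, n_inactive = 1200L,
                         vocab_size = 500L, n_enriched = 10L,
                         p_enriched_in_active = 0.9,
                         p_enriched_in_inactive = 0.1,
                         p_background = 0.05, seed = 1L) {
  cfg <- list(n_active = as.integer(n_active),
              n_inactive = as.integer(n_inactive),
              vocab_size = as.integer(vocab_size),
              n_enriched = as.integer(n_enriched),
              p_enriched_in_active = p_enriched_in_active,
              p_enriched_in_inactive = p_enriched_in_inactive,
              p_background = p_background, seed = as.integer(seed))
  probs <- c(cfg$p_enriched_in_active, cfg$p_enriched_in_inactive,
             cfg$p_background)
  if (any(probs < 0 | probs > 1))
    stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_active < 1L || cfg$n_inactive < 1L)
    stop("both classes must be non-empty", call. = FALSE)
  if (cfg$n_enriched > cfg$vocab_size)
    stop("n_enriched exceeds vocab_size", call. = FALSE)
  if (cfg$p_enriched_in_active < cfg$p_enriched_in_inactive)
    warning("p_enriched_in_active < p_enriched_in_inactive: ",
            "the planted signal is inverted", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic descriptor-level training set
#'
#' Labels are exact by construction; the same seed reproduces the dataset
#' byte for byte. A compound left with an empty set by the inclusion draws
#' receives one uniformly chosen background item so every descriptor set
#' is non-empty, as for any real molecule.
#'
#' @param cfg a [synth_config()].
#' @param activity_id name given to the planted activity.
#' @return List with `features` (named list of descriptor sets), `labeled`
#'   (a `labeled_set`) and `enriched` (the signal-carrying labels).
#' @export
make_descriptor_dataset <- function(cfg = synth_config(),
                                    activity_id = "synthetic") {
  stopifnot(inherits(cfg, "synth_config"))
  vocab <- sprintf("D%04d", seq_len(cfg$vocab_size))
  enriched <- vocab[seq_len(cfg$n_enriched)]
  n <- cfg$n_active + cfg$n_inactive
  ids <- sprintf("cmp%04d", seq_len(n))
  label <- rep(c("active", "inactive"), c(cfg$n_active, cfg$n_inactive))
  p_enr <- ifelse(label == "active", cfg$p_enriched_in_active,
                  cfg$p_enriched_in_inactive)
  features <- vector("list", n)
  with_seed(cfg$seed, {
    for (i in seq_len(n)) {
      inc_e <- stats::runif(cfg$n_enriched) < p_enr[i]
      inc_b <- stats::runif(cfg$vocab_size - cfg$n_enriched) <
        cfg$p_background
      d <- c(enriched[inc_e], vocab[-seq_len(cfg$n_enriched)][inc_b])
      if (!length(d)) d <- sample(vocab, 1L)
      features[[i]] <- sort(d)
    }
  })
  names(features) <- ids
  list(features = features,
       labeled = labeled_set(activity_id, ids, label),
       enriched = enriched)
}

# fragment library for assembling small valid druglike SMILES by chain
# concatenation; every token extends a linear chain and stays parseable
SMILES_FRAGMENTS <- c("C", "CC", "CO", "CN", "C(C)", "C(=O)", "CCO",
                      "c1ccccc1", "C(F)", "CS", "C(Cl)", "c1ccncc1",
                      "C(C)(C)", "CCN")

# activity-conferring substructure appended to active compounds
PLANTED_SUBSTRUCTURE <- "S(=O)(=O)N"

#' Generate a synthetic SMILES dataset with a planted active substructure
#'
#' Small valid druglike SMILES are assembled by concatenating fragments
#' from a fixed library into linear chains; active compounds additionally
#' carry a sulfonamide substructure, so some of its MNA descriptors are
#' strongly enriched among actives. The emitted files exercise the full
#' structure-parsing, descriptor, curation and modelling path end to end.
#'
#' @param n_active,n_inactive class sizes.
#' @param seed integer seed.
#' @param activity_id cell-line name used in the activity table.
#' @param n_fragments_range chain length range (fragments per compound).
#' @return List with `smiles` (data.frame `compound_id`, `smiles`) and
#'   `activity` (data.frame of raw activity records: IC50 values in nM
#'   below 10,000 for actives, above for inactives, ready for
#'   [build_labeled_sets()] with zero drops).
#' @export
make_smiles_dataset <- function(n_active = 30L, n_inactive = 60L, seed = 1L,
                                activity_id = "HL-60",
                                n_fragments_range = c(2L, 5L)) {
  n <- n_active + n_inactive
  ids <- sprintf("syn%03d", seq_len(n))
  label <- rep(c("active", "inactive"), c(n_active, n_inactive))
  with_seed(seed, {
    smiles <- vapply(seq_len(n), function(i) {
      k <- sample(seq(n_fragments_range[1L], n_fragments_range[2L]), 1L)
      chain <- paste(sample(SMILES_FRAGMENTS, k, replace = TRUE),
                     collapse = "")
      if (label[i] == "active") paste0(chain, PLANTED_SUBSTRUCTURE)
      else chain
    }, character(1))
    value <- ifelse(label == "active",
                    stats::runif(n, 10, 5000),
                    stats::runif(n, 20000, 100000))
  })
  activity <- data.frame(compound_id = ids, activity_id = activity_id,
                         endpoint = "IC50", value = value, units = "nM",
                         failure_reason = "", stringsAsFactors = FALSE)
  list(smiles = data.frame(compound_id = ids, smiles = smiles,
                           stringsAsFactors = FALSE),
       activity = activity)
}
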