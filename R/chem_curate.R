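# Curation pipeline: deduplication, conformer attachment, yield filtering,
# stratified and component-held-out splitting.  Every stage reports counts
# and per-record drop reasons; counts are non-increasing along the pipeline.

new_curation_report <- function(input) {
  structure(list(counts = c(input = as.integer(input)),
                 dropped = data.frame(record_id = character(0),
                                      stage = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)),
            class = "mvrxn_report")
}

report_stage <- function(rep, stage, count, dropped = NULL) {
  if (count > utils::tail(rep$counts, 1L))
    stop("invariant violation: curation counts must be non-increasing")
  rep$counts[stage] <- as.integer(count)
  if (!is.null(dropped) && nrow(dropped)) {
    dropped$stage <- stage
    rep$dropped <- rbind(rep$dropped, dropped[, c("record_id", "stage", "reason")])
  }
  rep
}

#' @export
print.mvrxn_report <- function(x, ...) {
  cat("<mvrxn_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  if (nrow(x$dropped)) cat("  dropped:", nrow(x$dropped), "records\n")
  invisible(x)
}

#' Deduplicate a reaction dataset
#'
#' Records with identical canonical reaction keys collapse to one.  Among
#' duplicates a record with a yield is preferred over one without; ties
#' resolve to the first occurrence.  Idempotent.
#'
#' @param d an `mvrxn_dataset` whose records are canonicalized.
#' @return `list(dataset, report)`.
#' @export
deduplicate_dataset <- function(d) {
  rep <- new_curation_report(length(d$records))
  keys <- vapply(d$records, reaction_key, character(1))
  keep <- logical(length(keys))
  dropped <- character(0)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    has_yield <- !is.na(vapply(d$records[idx], function(r) r$yield_pct,
                               numeric(1)))
    chosen <- if (any(has_yield)) idx[which(has_yield)[1L]] else idx[1L]
    keep[chosen] <- TRUE
    dropped <- c(dropped, names(d$records)[setdiff(idx, chosen)])
  }
  out <- subset_dataset(d, names(d$records)[keep])
  dd <- data.frame(record_id = dropped,
                   reason = rep("duplicate reaction key", length(dropped)),
                   stringsAsFactors = FALSE)
  rep <- report_stage(rep, "after_dedup", length(out$records), dd)
  list(dataset = out, report = rep)
}

#' Attach one conformer per molecule
#'
#' Applies a conformer-embedder hook to every molecule.  A reaction with at
#' least one embedding failure is dropped entirely (the retention rule of
#' the curation pipeline).  Coordinates are deterministic given `seed`: the
#' per-molecule seed is derived from `seed` and the molecule's canonical
#' SMILES, so identical molecules always receive identical conformers.
#'
#' @param d an `mvrxn_dataset`.
#' @param embedder function `(smiles, seed) -> m x 3 matrix or NULL` on
#'   failure; see [rule_based_embedder()] and [openbabel_embedder()].
#' @param seed integer seed.
#' @return `list(dataset, report)`.
#' @export
attach_conformers <- function(d, embedder = rule_based_embedder(), seed = 1L) {
  rep <- new_curation_report(length(d$records))
  keep <- character(0)
  dropped <- data.frame(record_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (id in names(d$records)) {
    r <- d$records[[id]]
    ok <- TRUE
    embed_role <- function(mols) {
      lapply(mols, function(m) {
        mseed <- (as.numeric(seed) + stable_string_hash(m$smiles)) %% 2147483647
        co <- embedder(m$smiles, as.integer(mseed))
        if (is.null(co) || !all(is.finite(co)) ||
            nrow(co) != length(m$atoms)) {
          ok <<- FALSE
          return(m)
        }
        m$coords <- co
        m
      })
    }
    r$reactants <- embed_role(r$reactants)
    r$agents <- embed_role(r$agents)
    r$products <- embed_role(r$products)
    if (ok) {
      d$records[[id]] <- r
      keep <- c(keep, id)
    } else {
      dropped <- rbind(dropped, data.frame(
        record_id = id, reason = "conformer embedding failed",
        stringsAsFactors = FALSE))
    }
  }
  out <- subset_dataset(d, keep)
  rep <- report_stage(rep, "after_conformers", length(keep), dropped)
  list(dataset = out, report = rep)
}

#' Filter records by yield validity, with optional low-yield sampling
#'
#' A yield is valid when numeric and in (0, 100]; records with missing or
#' invalid yields are removed.  In `"augment"` mode a seeded random
#' fraction `low_fraction` of the retained records with yield below
#' `low_cut` is kept (emulating low-yield subsampling when augmenting a
#' biased corpus); `"plain"` mode keeps them all.
#'
#' @param d an `mvrxn_dataset`.
#' @param low_cut yield threshold in (0, 100], default 50.
#' @param low_fraction fraction of low-yield records kept in augment mode.
#' @param seed integer seed for the sampler.
#' @param mode `"plain"` or `"augment"`.
#' @return `list(dataset, report)`.
#' @export
filter_by_yield <- function(d, low_cut = 50, low_fraction = 1.0, seed = 1L,
                            mode = c("plain", "augment")) {
  mode <- match.arg(mode)
  stopifnot(low_cut > 0, low_cut <= 100)
  if (low_fraction < 0 || low_fraction > 1)
    stop("config error: low_fraction must lie in [0, 1]")
  rep <- new_curation_report(length(d$records))
  y <- dataset_yields(d)
  valid <- !is.na(y) & y > 0 & y <= 100
  dd <- data.frame(record_id = names(d$records)[!valid],
                   reason = rep("missing or invalid yield", sum(!valid)),
                   stringsAsFactors = FALSE)
  rep <- report_stage(rep, "after_yield_validity", sum(valid), dd)
  keep <- names(d$records)[valid]
  if (mode == "augment") {
    ylow <- y[keep] < low_cut
    low_ids <- keep[ylow]
    n_keep <- round(length(low_ids) * low_fraction)
    withr::with_seed(as.integer(seed), {
      kept_low <- sample(low_ids, n_keep)
    })
    drop_low <- setdiff(low_ids, kept_low)
    keep <- keep[!(keep %in% drop_low)]
    dd <- data.frame(record_id = drop_low,
                     reason = rep("low-yield subsampling", length(drop_low)),
                     stringsAsFactors = FALSE)
    rep <- report_stage(rep, "after_low_yield_sampling", length(keep), dd)
  }
  list(dataset = subset_dataset(d, keep), report = rep)
}

# evenly interleaved assignment pattern for a ratio triple, by largest
# remainder; e.g. 18:1:1 -> one valid and one test slot spread over 20
split_pattern <- function(ratio) {
  L <- sum(ratio)
  splits <- c("train", "valid", "test")
  assigned <- c(0, 0, 0)
  pattern <- character(L)
  for (k in seq_len(L)) {
    deficit <- ratio * k / L - assigned
    j <- which.max(deficit)
    pattern[k] <- splits[j]
    assigned[j] <- assigned[j] + 1
  }
  pattern
}

#' Stratified train/valid/test split by yield
#'
#' Records are binned into `n_bins` equal-width yield bins on [0, 100],
#' shuffled within bins (seeded), and assigned by walking an evenly
#' interleaved ratio pattern continuously across bins.  Both the global
#' and the per-bin train/valid/test proportions match the ratio to within
#' one record.  Records without yields fall into a single bin, which
#' degrades gracefully to a plain random ratio split.
#'
#' @param d an `mvrxn_dataset`.
#' @param ratio integer triple, default `c(18, 1, 1)`.
#' @param n_bins number of equal-width yield bins, default 10.
#' @param seed integer seed.
#' @return the dataset with `split_labels` set.
#' @export
stratified_split <- function(d, ratio = c(18L, 1L, 1L), n_bins = 10L,
                             seed = 1L) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0), sum(ratio) > 0)
  n <- length(d$records)
  if (n < sum(ratio))
    stop("split error: ", n, " records cannot honour a ",
         paste(ratio, collapse = ":"), " split")
  y <- dataset_yields(d)
  if (all(is.na(y))) {
    bins <- rep(1L, n)
  } else {
    edges <- seq(0, 100, length.out = n_bins + 1L)
    bins <- findInterval(y, edges, rightmost.closed = TRUE)
    bins[is.na(bins)] <- n_bins + 1L
  }
  pattern <- split_pattern(ratio)
  L <- length(pattern)
  labels <- character(n)
  names(labels) <- names(d$records)
  pos <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in sort(unique(bins))) {
      idx <- which(bins == b)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        labels[i] <- pattern[(pos %% L) + 1L]
        pos <- pos + 1L
      }
    }
  })
  d$split_labels <- labels
  d
}

#' Hold out reactions containing specific components
#'
#' Every reaction containing a held-out component (canonical SMILES, in the
#' stated role) is labelled `test`; all others `train`.  By construction no
#' training reaction contains any held-out component.
#'
#' @param d an `mvrxn_dataset`.
#' @param held_out character vector of SMILES to hold out (canonicalized).
#' @param role `"reactants"`, `"agents"`, `"products"`, or `"any"`.
#' @return the dataset with `split_labels` set to train/test.
#' @export
split_by_component <- function(d, held_out,
                               role = c("any", "reactants", "agents",
                                        "products")) {
  role <- match.arg(role)
  stopifnot(length(held_out) >= 1L)
  held_out <- canonical_smiles(held_out)
  if (anyNA(held_out))
    stop("validity error: unparseable held-out SMILES")
  role_smiles <- function(r) {
    mols <- switch(role,
                   any = c(r$reactants, r$agents, r$products),
                   reactants = r$reactants, agents = r$agents,
                   products = r$products)
    vapply(mols, function(m) m$smiles, character(1))
  }
  occurs <- vapply(d$records, function(r) any(held_out %in% role_smiles(r)),
                   logical(1))
  present <- unique(unlist(lapply(d$records, role_smiles)))
  missing <- setdiff(held_out, present)
  if (length(missing))
    stop("split error: held-out SMILES not present in dataset (role ", role,
         "): ", paste(missing, collapse = ", "))
  labels <- ifelse(occurs, "test", "train")
  names(labels) <- names(d$records)
  d$split_labels <- labels
  d
}

#' Run the full curation pipeline
#'
#' Canonicalize, deduplicate, attach conformers, and (optionally) filter by
#' yield, returning the curated dataset plus a merged stage-count report.
#'
#' @param d an `mvrxn_dataset`.
#' @param embedder conformer embedder hook.
#' @param dedup run deduplication (default TRUE).
#' @param yield_filter drop records without valid yields (default FALSE;
#'   self-supervised corpora keep unlabelled reactions).
#' @inheritParams filter_by_yield
#' @return `list(dataset, report)`.
#' @export
curate_dataset <- function(d, embedder = rule_based_embedder(), dedup = TRUE,
                           yield_filter = FALSE, low_cut = 50,
                           low_fraction = 1.0, seed = 1L,
                           mode = c("plain", "augment")) {
  rep <- new_curation_report(length(d$records))
  ok <- logical(length(d$records))
  for (i in seq_along(d$records)) {
    r <- tryCatch(canonicalize_reaction(d$records[[i]]), error = function(e) NULL)
    if (!is.null(r)) {
      d$records[[i]] <- r
      ok[i] <- TRUE
    }
  }
  dd <- data.frame(record_id = names(d$records)[!ok],
                   reason = rep("invalid SMILES", sum(!ok)),
                   stringsAsFactors = FALSE)
  d <- subset_dataset(d, names(d$records)[ok])
  rep <- report_stage(rep, "after_validity", length(d$records), dd)
  if (dedup) {
    step <- deduplicate_dataset(d)
    d <- step$dataset
    rep <- report_stage(rep, "after_dedup", length(d$records),
                        step$report$dropped)
  }
  step <- attach_conformers(d, embedder, seed)
  d <- step$dataset
  rep <- report_stage(rep, "after_conformers", length(d$records),
                      step$report$dropped)
  if (yield_filter) {
    step <- filter_by_yield(d, low_cut, low_fraction, seed, mode)
    d <- step$dataset
    rep <- report_stage(rep, "after_yield_filter", length(d$records),
                        step$report$dropped)
  }
  list(dataset = d, report = rep)
}
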