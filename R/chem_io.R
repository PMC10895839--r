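# Dataset I/O.  A dataset on disk is a directory:
#   reactions.csv   record_id, reaction_smiles, yield_pct [, split]
#   conformers.sdf  one zero-bond V2000 molblock per molecule, tagged with
#                   record_id and molecule index (canonical order)
#   provenance.json free-text metadata
# Reaction-SMILES line files (one reaction per line) are also supported.

#' Write a reaction dataset to a directory
#'
#' @param d an `mvrxn_dataset`.
#' @param path directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- names(d$records)
  df <- data.frame(
    record_id = ids,
    reaction_smiles = vapply(d$records, reaction_smiles, character(1)),
    yield_pct = vapply(d$records, function(r) r$yield_pct, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(d$split_labels)) df$split <- unname(d$split_labels[ids])
  utils::write.csv(df, file.path(path, "reactions.csv"), row.names = FALSE)
  has_coords <- any(vapply(d$records, function(r) {
    any(vapply(reaction_molecules(r), function(m) !is.null(m$coords),
               logical(1)))
  }, logical(1)))
  if (has_coords) write_conformer_sdf(d, file.path(path, "conformers.sdf"))
  jsonlite::write_json(list(provenance = d$provenance),
                       file.path(path, "provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a reaction dataset from a directory
#'
#' @param path directory written by [write_dataset()].
#' @param require_yields error when the yield column is absent or empty
#'   (supervised mode).
#' @return an `mvrxn_dataset`.
#' @export
load_dataset <- function(path, require_yields = FALSE) {
  csv <- file.path(path, "reactions.csv")
  if (!file.exists(csv)) stop("I/O error: no reactions.csv under ", path)
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("record_id", "reaction_smiles")
  if (!all(need %in% names(df)))
    stop("I/O error: reactions.csv must have columns ",
         paste(need, collapse = ", "))
  if (require_yields &&
      (!"yield_pct" %in% names(df) || all(is.na(df$yield_pct))))
    stop("I/O error: supervised mode requires a yield_pct column with values")
  if (!"yield_pct" %in% names(df)) df$yield_pct <- NA_real_
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    records[[i]] <- tryCatch(
      parse_reaction_smiles(df$reaction_smiles[i],
                            record_id = df$record_id[i],
                            yield_pct = df$yield_pct[i]),
      error = function(e) stop("I/O error at reactions.csv line ", i + 1L,
                               ": ", conditionMessage(e)))
  }
  split_labels <- NULL
  if ("split" %in% names(df) && !all(is.na(df$split))) {
    split_labels <- stats::setNames(df$split, df$record_id)
  }
  prov <- ""
  pj <- file.path(path, "provenance.json")
  if (file.exists(pj)) prov <- jsonlite::fromJSON(pj)$provenance %||% ""
  d <- reaction_dataset(records, provenance = prov,
                        split_labels = split_labels)
  sdf <- file.path(path, "conformers.sdf")
  if (file.exists(sdf)) d <- read_conformer_sdf(d, sdf)
  d
}

#' Read reactions from a reaction-SMILES line file
#'
#' One `"reactants>agents>products"` string per line; blank lines skipped.
#' @param path file path.
#' @return an `mvrxn_dataset`.
#' @export
read_reaction_lines <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  records <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    tryCatch(parse_reaction_smiles(trimws(lines[i]),
                                   record_id = sprintf("r%06d", k)),
             error = function(e) stop("I/O error at ", path, " line ", i,
                                      ": ", conditionMessage(e)))
  })
  reaction_dataset(records, provenance = paste("lines:", path))
}

# ---- SDF sidecar (zero-bond V2000 molblocks) -------------------------------

write_conformer_sdf <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(d$records)) {
    mols <- reaction_molecules(d$records[[id]])
    for (k in seq_along(mols)) {
      m <- mols[[k]]
      if (is.null(m$coords)) next
      na <- length(m$atoms)
      writeLines(c(
        paste0(id, "#", k),
        "  mvrxn", "",
        sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, 0L),
        vapply(seq_len(na), function(a) {
          sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  m$coords[a, 1L], m$coords[a, 2L], m$coords[a, 3L],
                  m$atoms[a])
        }, character(1)),
        "M  END",
        ">  <record_id>", id, "",
        ">  <mol_index>", as.character(k), "",
        "$$$$"), con)
    }
  }
  invisible(path)
}

read_conformer_sdf <- function(d, path) {
  lines <- readLines(path)
  starts <- c(1L, which(lines == "$$$$") + 1L)
  starts <- starts[starts <= length(lines)]
  for (s in starts) {
    if (s + 3L > length(lines)) break
    title <- lines[s]
    counts <- lines[s + 3L]
    na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    if (is.na(na)) stop("I/O error: malformed counts line at ", path,
                        " line ", s + 3L)
    parts <- strsplit(title, "#", fixed = TRUE)[[1L]]
    id <- paste(parts[-length(parts)], collapse = "#")
    k <- as.integer(parts[length(parts)])
    atom_lines <- lines[s + 3L + seq_len(na)]
    co <- t(vapply(atom_lines, function(l) {
      c(as.numeric(substr(l, 1L, 10L)), as.numeric(substr(l, 11L, 20L)),
        as.numeric(substr(l, 21L, 30L)))
    }, numeric(3)))
    rownames(co) <- NULL
    if (!id %in% names(d$records))
      stop("I/O error: conformer for unknown record '", id, "'")
    r <- d$records[[id]]
    mols <- reaction_molecules(r)
    if (k > length(mols) || nrow(co) != length(mols[[k]]$atoms))
      stop("I/O error: conformer atom count mismatch for record '", id,
           "' molecule ", k)
    d$records[[id]] <- assign_conformer(r, k, co)
  }
  d
}

# put coords onto the k-th molecule in canonical order
assign_conformer <- function(r, k, coords) {
  ord_idx <- function(mols) order(vapply(mols, function(m) m$smiles,
                                         character(1)), method = "radix")
  nr <- length(r$reactants); na <- length(r$agents)
  if (k <= nr) {
    j <- ord_idx(r$reactants)[k]
    r$reactants[[j]]$coords <- coords
  } else if (k <= nr + na) {
    j <- ord_idx(r$agents)[k - nr]
    r$agents[[j]]$coords <- coords
  } else {
    j <- ord_idx(r$products)[k - nr - na]
    r$products[[j]]$coords <- coords
  }
  r
}

#' Write a curation report as JSON
#' @param rep an `mvrxn_report`; `path` file path.
#' @export
write_report <- function(rep, path) {
  jsonlite::write_json(list(counts = as.list(rep$counts),
                            dropped = rep$dropped),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
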