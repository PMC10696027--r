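# Molecule curation: canonicalisation, merging, deduplication.
#
# All SMILES handling is delegated to OpenBabel (`obabel` on the PATH),
# batched through temporary files. Canonical output uses the writer option
# `-xi` so stereo descriptors (chirality, cis/trans) are dropped, and `-r`
# keeps only the largest fragment of multi-component (salt/mixture) inputs.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("OpenBabel executable 'obabel' not found on the PATH")
  p
}

# Batch-convert SMILES; returns character vector aligned with `smiles`,
# NA where OpenBabel could not parse the input. `args` are extra obabel
# flags (e.g. "-xi", "-r").
obabel_convert <- function(smiles, out_format, args = character()) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = paste0(".", out_format))
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  # tag each row with its index so skipped (unparseable) rows are traceable
  writeLines(paste(smiles, paste0("row", seq_len(n))), infile)
  status <- suppressWarnings(system2(
    obabel_path(),
    c(infile, paste0("-o", out_format), "-e", args),
    stdout = outfile, stderr = FALSE
  ))
  if (!file.exists(outfile)) stop("obabel conversion produced no output")
  readLines(outfile, warn = FALSE)
}

#' Canonicalise SMILES strings, stripping stereochemistry
#'
#' Converts each SMILES to OpenBabel's canonical form with all stereo
#' descriptors (atom chirality, double-bond cis/trans) removed, so that two
#' representations of the same 2D molecular graph map to the same string.
#' Multi-fragment inputs (salts, mixtures) are reduced to their largest
#' fragment.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of canonical stereo-free SMILES, `NA` for
#'   unparseable inputs.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "C(C)O"))   # identical outputs
#' canonicalize_smiles("C[C@@H](N)O")       # stereo removed
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0) return(character(0))
  lines <- obabel_convert(smiles, "can", c("-xi", "-r"))
  out <- rep(NA_character_, n)
  if (length(lines)) {
    parts <- strsplit(lines, "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2 && grepl("^row[0-9]+$", p[2])) {
        idx <- as.integer(sub("^row", "", p[2]))
        out[idx] <- p[1]
      }
    }
  }
  out
}

#' Canonicalise a single SMILES string
#'
#' Scalar strict variant of [canonicalize_smiles()]: unparseable input is an
#' error naming the offending string. Canonicalisation is idempotent:
#' `canonicalize(canonicalize(s)) == canonicalize(s)`.
#'
#' @param smiles a single SMILES string.
#' @return The canonical stereo-free SMILES.
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  out <- canonicalize_smiles(smiles)
  if (is.na(out)) stop("unparseable SMILES: '", smiles, "'")
  out
}

#' Construct a molecule set
#'
#' A molecule set is a data frame of curated molecule records with columns
#' `id`, `smiles_raw`, `smiles_canonical`, `label` (one of `"toxic"`,
#' `"nontoxic"`, `"unlabelled"`) and `source`. Labels outside the
#' vocabulary are mapped to `"unlabelled"` (and are ignored by the
#' classifier).
#'
#' @param smiles character vector of raw SMILES.
#' @param label character vector of labels (recycled); `"toxic"` or
#'   `"nontoxic"`, anything else becomes `"unlabelled"`.
#' @param source character vector of source tags (recycled).
#' @param id optional ids; defaults to `mol1, mol2, ...`.
#' @param canonical pre-computed canonical SMILES (skips re-canonicalising).
#' @return A `molecule_set` data frame; rows whose SMILES fail to parse are
#'   dropped with a message.
#' @export
molecule_set <- function(smiles, label = "unlabelled", source = "user",
                         id = NULL, canonical = NULL) {
  n <- length(smiles)
  label <- rep_len(as.character(label), n)
  label[!label %in% c("toxic", "nontoxic")] <- "unlabelled"
  source <- rep_len(as.character(source), n)
  id <- if (is.null(id)) paste0("mol", seq_len(n)) else rep_len(as.character(id), n)
  canonical <- if (is.null(canonical)) canonicalize_smiles(smiles) else canonical
  bad <- is.na(canonical)
  if (any(bad)) {
    message(sum(bad), " unparseable SMILES row(s) skipped")
  }
  out <- data.frame(
    id = id[!bad], smiles_raw = smiles[!bad],
    smiles_canonical = canonical[!bad],
    label = label[!bad], source = source[!bad],
    stringsAsFactors = FALSE
  )
  class(out) <- c("molecule_set", "data.frame")
  out
}

#' Read a labelled SMILES table
#'
#' Reads molecules from a CSV file with a header containing at least a
#' `smiles` column (optionally `label`, `source`, `id`), or from a `.smi`
#' file (`SMILES whitespace id` per line, no labels). All records are
#' canonicalised; unparseable rows are skipped with a message.
#'
#' @param path path to the input file.
#' @param format `"csv"` or `"smi"`; default guessed from the extension.
#' @return A `molecule_set`.
#' @export
read_smiles_table <- function(path, format = c("auto", "csv", "smi")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.smi$", path, ignore.case = TRUE)) "smi" else "csv"
  }
  stopifnot(file.exists(path))
  if (format == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (nrow(tab) == 0) return(molecule_set(character(0)))
    if (!"smiles" %in% names(tab)) {
      stop("input CSV has no 'smiles' column: ", path)
    }
    molecule_set(
      smiles = tab$smiles,
      label = if ("label" %in% names(tab)) tab$label else "unlabelled",
      source = if ("source" %in% names(tab)) tab$source else basename(path),
      id = if ("id" %in% names(tab)) tab$id else NULL
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(molecule_set(character(0)))
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[`, "", 1)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
    if (anyNA(ids)) ids <- NULL
    molecule_set(smiles, source = basename(path), id = ids)
  }
}

#' Merge molecule sets and remove duplicates and label conflicts
#'
#' Concatenates the sets, collapses records sharing a canonical SMILES, and
#' drops entirely any canonical SMILES observed with conflicting labels
#' (toxic vs nontoxic), logging them in a conflict report. Same-label
#' duplicates collapse to one record keeping the first-seen id/source; an
#' unlabelled duplicate never conflicts with a labelled one (the label
#' wins).
#'
#' @param sets a list of `molecule_set` objects (or a single one).
#' @return A list with elements `molecules` (deduplicated `molecule_set`)
#'   and `conflicts` (a `conflict_report`: data frame of discarded
#'   canonical SMILES with the labels and sources seen, plus
#'   `n_discarded`).
#' @export
merge_and_deduplicate <- function(sets) {
  if (inherits(sets, "molecule_set")) sets <- list(sets)
  all <- do.call(rbind, lapply(sets, as.data.frame))
  if (is.null(all) || nrow(all) == 0) {
    mols <- molecule_set(character(0))
    rep <- structure(
      list(discarded = data.frame(smiles_canonical = character(0),
                                  labels = character(0),
                                  sources = character(0),
                                  stringsAsFactors = FALSE),
           n_discarded = 0L),
      class = "conflict_report"
    )
    return(list(molecules = mols, conflicts = rep))
  }
  keys <- unique(all$smiles_canonical)
  keep <- logical(length(keys))
  label_out <- character(length(keys))
  first_row <- integer(length(keys))
  disc_lab <- character(0); disc_src <- character(0); disc_key <- character(0)
  for (k in seq_along(keys)) {
    rows <- which(all$smiles_canonical == keys[k])
    labs <- unique(all$label[rows])
    hard <- setdiff(labs, "unlabelled")
    if (length(hard) > 1) {
      disc_key <- c(disc_key, keys[k])
      disc_lab <- c(disc_lab, paste(sort(labs), collapse = "|"))
      disc_src <- c(disc_src, paste(unique(all$source[rows]), collapse = "|"))
      next
    }
    keep[k] <- TRUE
    label_out[k] <- if (length(hard) == 1) hard else "unlabelled"
    first_row[k] <- rows[1]
  }
  kept <- all[first_row[keep], , drop = FALSE]
  kept$label <- label_out[keep]
  rownames(kept) <- NULL
  class(kept) <- c("molecule_set", "data.frame")
  rep <- structure(
    list(discarded = data.frame(smiles_canonical = disc_key, labels = disc_lab,
                                sources = disc_src, stringsAsFactors = FALSE),
         n_discarded = length(disc_key)),
    class = "conflict_report"
  )
  list(molecules = kept, conflicts = rep)
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("<molecule_set> ", nrow(x), " molecules (",
      sum(x$label == "toxic"), " toxic, ",
      sum(x$label == "nontoxic"), " nontoxic, ",
      sum(x$label == "unlabelled"), " unlabelled)\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5), ...)
  invisible(x)
}

#' @export
print.conflict_report <- function(x, ...) {
  cat("<conflict_report> ", x$n_discarded,
      " canonical SMILES discarded for conflicting labels\n", sep = "")
  if (x$n_discarded > 0) print(x$discarded, ...)
  invisible(x)
}

#' Write a curated molecule set and conflict report
#'
#' @param molecules a `molecule_set`.
#' @param conflicts a `conflict_report` (optional).
#' @param csv_path output CSV path (`smiles_canonical,label,source`).
#' @param conflicts_path optional JSON path for the conflict report.
#' @return `csv_path`, invisibly.
#' @export
write_molecule_set <- function(molecules, csv_path, conflicts = NULL,
                               conflicts_path = NULL) {
  write.csv(as.data.frame(molecules)[, c("id", "smiles_canonical", "label", "source")],
            csv_path, row.names = FALSE)
  if (!is.null(conflicts) && !is.null(conflicts_path)) {
    jsonlite::write_json(
      list(n_discarded = conflicts$n_discarded, discarded = conflicts$discarded),
      conflicts_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
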