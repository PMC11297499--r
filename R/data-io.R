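# Reading, validating and writing paired-chain TCR-epitope data.

# canonical column order for dataset files
.dataset_cols <- c("peptide", "A1", "A2", "A3", "B1", "B2", "B3",
                   "binder", "partition", "origin")

.default_dialect <- function() {
  stats::setNames(as.list(.dataset_cols), .dataset_cols)
}

#' Read a paired-chain TCR-epitope dataset
#'
#' One record per row: a peptide, the six CDR sequences (CDR1/2/3 of the
#' alpha and beta chains), a binary binder label, and optionally a fold
#' partition and an origin tag. Default column names follow the
#' `peptide, A1, A2, A3, B1, B2, B3, binder, partition` convention of the
#' public paired-chain benchmark files; other headers are accepted via
#' `dialect`.
#'
#' Sequences are uppercased. Rows containing characters outside the
#' 20-letter amino-acid alphabet are an error by default (the offending
#' row numbers are reported); with `on_invalid = "drop"` they are dropped
#' with a warning instead. Duplicate records (same peptide + six CDRs +
#' label) are collapsed to one with a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named list mapping canonical column names to the names
#'   used in the file, e.g. `list(peptide = "antigen", binder = "label")`.
#'   Unmentioned columns keep their canonical names.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @param on_invalid `"error"` (default) or `"drop"` for rows with
#'   non-standard residues.
#' @return A tibble with columns `peptide, A1..B3, binder, partition,
#'   origin` (class `tcr_dataset`).
#' @export
read_tcr_dataset <- function(path, dialect = list(), delim = NULL,
                             on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  raw <- read_delim_auto(path, delim)
  if (nrow(raw) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  d <- utils::modifyList(.default_dialect(), dialect)
  required <- c("peptide", cdr_slots(), "binder")
  for (col in required) {
    if (!d[[col]] %in% names(raw)) {
      stop("missing required column '", d[[col]], "' in ", path,
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    peptide = toupper(as.character(raw[[d$peptide]])),
    A1 = toupper(as.character(raw[[d$A1]])),
    A2 = toupper(as.character(raw[[d$A2]])),
    A3 = toupper(as.character(raw[[d$A3]])),
    B1 = toupper(as.character(raw[[d$B1]])),
    B2 = toupper(as.character(raw[[d$B2]])),
    B3 = toupper(as.character(raw[[d$B3]])),
    binder = as.integer(raw[[d$binder]])
  )
  out$partition <- if (d$partition %in% names(raw)) {
    as.integer(raw[[d$partition]])
  } else NA_integer_
  out$origin <- if (d$origin %in% names(raw)) {
    as.character(raw[[d$origin]])
  } else ifelse(out$binder == 1L, "positive_db", "shuffled_negative")
  validate_tcr_dataset(out, on_invalid = on_invalid)
}

#' Validate a dataset tibble
#'
#' Enforces the record invariants: all six CDRs and the peptide present
#' and drawn from the amino-acid alphabet, labels in \{0, 1\}, duplicates
#' collapsed.
#'
#' @param data Tibble with the canonical columns.
#' @param on_invalid `"error"` or `"drop"` for rows failing sequence
#'   validation.
#' @return The validated tibble, classed `tcr_dataset`.
#' @export
validate_tcr_dataset <- function(data, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  seq_cols <- seq_slots()
  ok <- Reduce(`&`, lapply(seq_cols, function(s) is_valid_aa(data[[s]])))
  if (!all(ok)) {
    bad <- which(!ok)
    if (on_invalid == "error") {
      stop("invalid residues (outside ACDEFGHIKLMNPQRSTVWY) in rows: ",
           paste(utils::head(bad, 20L), collapse = ", "),
           if (length(bad) > 20L) " ..." else "", call. = FALSE)
    }
    warning(length(bad), " row(s) with invalid residues dropped",
            call. = FALSE)
    data <- data[ok, , drop = FALSE]
    if (nrow(data) == 0L) stop("no valid rows remain", call. = FALSE)
  }
  if (!all(data$binder %in% c(0L, 1L))) {
    stop("binder labels must be 0 or 1", call. = FALSE)
  }
  key <- do.call(paste, c(data[c(seq_cols, "binder")], sep = "|"))
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate record(s) collapsed", call. = FALSE)
    data <- data[!duplicated(key), , drop = FALSE]
  }
  class(data) <- c("tcr_dataset", class(tibble::tibble()))
  data
}

#' Write a dataset to delimited text
#'
#' Stable canonical column order (`peptide, A1..B3, binder, partition,
#' origin`); a write/read/write cycle is byte-identical.
#'
#' @param data Dataset tibble.
#' @param path Output path; `.tsv` extension selects tab, otherwise comma.
#' @return Invisibly, `path`.
#' @export
write_tcr_dataset <- function(data, path) {
  cols <- intersect(.dataset_cols, names(data))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(data[cols], path, delim = delim, na = "")
  invisible(path)
}

#' Read a negative-control TCR pool
#'
#' Control pools hold TCRs without epitope labels (healthy-donor
#' repertoires): the same six CDR columns, no peptide or binder column.
#' Duplicate six-tuples are removed with a message reporting the count.
#'
#' @inheritParams read_tcr_dataset
#' @return Tibble with columns `A1..B3` (class `tcr_control_pool`).
#' @export
read_control_pool <- function(path, dialect = list(), delim = NULL) {
  raw <- read_delim_auto(path, delim)
  if (nrow(raw) == 0L) stop("empty control-pool file: ", path, call. = FALSE)
  d <- utils::modifyList(.default_dialect(), dialect)
  for (col in cdr_slots()) {
    if (!d[[col]] %in% names(raw)) {
      stop("missing required column '", d[[col]], "' in ", path,
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(
    lapply(stats::setNames(cdr_slots(), cdr_slots()),
           function(s) toupper(as.character(raw[[d[[s]]]])))
  )
  validate_control_pool(out)
}

#' Validate a control pool
#' @param pool Tibble with columns `A1..B3`.
#' @return Deduplicated validated tibble, classed `tcr_control_pool`.
#' @export
validate_control_pool <- function(pool) {
  ok <- Reduce(`&`, lapply(cdr_slots(), function(s) is_valid_aa(pool[[s]])))
  if (!all(ok)) {
    stop("invalid residues in control pool rows: ",
         paste(utils::head(which(!ok), 20L), collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(pool[cdr_slots()], sep = "|"))
  ndup <- sum(duplicated(key))
  if (ndup > 0L) {
    message(ndup, " duplicate(s) removed from control pool")
    pool <- pool[!duplicated(key), , drop = FALSE]
  }
  class(pool) <- c("tcr_control_pool", class(tibble::tibble()))
  pool
}

#' Write a control pool
#' @param pool Control-pool tibble.
#' @param path Output path (`.tsv` for tab, else comma).
#' @return Invisibly, `path`.
#' @export
write_control_pool <- function(pool, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(pool[cdr_slots()], path, delim = delim)
  invisible(path)
}

# shared delimited reader with comma/tab auto-detection
read_delim_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Construct a residue-distance map
#'
#' A distance map pairs every peptide residue with every CDR-beta residue
#' of one TCR-pMHC complex and records their spatial distance in
#' angstroms.
#'
#' @param complex_id Identifier, e.g. a PDB code.
#' @param peptide_seq,cdrb_seq The two sequences.
#' @param d Numeric matrix, `nchar(peptide_seq)` x `nchar(cdrb_seq)`,
#'   non-negative distances in angstroms.
#' @return Object of class `distance_map`.
#' @export
distance_map <- function(complex_id, peptide_seq, cdrb_seq, d) {
  peptide_seq <- toupper(peptide_seq); cdrb_seq <- toupper(cdrb_seq)
  stopifnot(is_valid_aa(peptide_seq), is_valid_aa(cdrb_seq))
  d <- as.matrix(d)
  if (nrow(d) != nchar(peptide_seq) || ncol(d) != nchar(cdrb_seq)) {
    stop("distance matrix shape ", nrow(d), "x", ncol(d),
         " does not match sequence lengths ", nchar(peptide_seq), "x",
         nchar(cdrb_seq), call. = FALSE)
  }
  if (any(d < 0) || any(!is.finite(d))) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  dimnames(d) <- list(strsplit(peptide_seq, "")[[1L]],
                      strsplit(cdrb_seq, "")[[1L]])
  structure(list(complex_id = complex_id, peptide_seq = peptide_seq,
                 cdrb_seq = cdrb_seq, d = d),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("<distance_map>", x$complex_id, ":", x$peptide_seq, "x", x$cdrb_seq,
      sprintf("(%d x %d), mean %.2f A\n", nrow(x$d), ncol(x$d), mean(x$d)))
  invisible(x)
}

#' Read a distance map from delimited text
#'
#' Format: two header lines `#complex_id<TAB>id` optional and
#' `#peptide<TAB>SEQ`, `#cdrb<TAB>SEQ`, followed by the numeric matrix
#' (tab-delimited, one peptide residue per row).
#'
#' @param path Input path.
#' @return A `distance_map`.
#' @export
read_distance_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    h <- grep(paste0("^#", key, "\t"), hdr, value = TRUE)
    if (length(h) != 1L) stop("missing header line #", key, " in ", path,
                              call. = FALSE)
    sub(paste0("^#", key, "\t"), "", h)
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  d <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  distance_map(get("complex_id"), get("peptide"), get("cdrb"), d)
}

#' Write a distance map to delimited text
#' @param dm A `distance_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_map <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#complex_id\t", dm$complex_id),
               paste0("#peptide\t", dm$peptide_seq),
               paste0("#cdrb\t", dm$cdrb_seq)), con)
  utils::write.table(dm$d, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Distance map from residue coordinates
#'
#' Computes `d[i, j]` as the Euclidean distance between the
#' representative atoms of peptide residue `i` and CDR-beta residue `j`.
#'
#' @param complex_id Identifier.
#' @param peptide_seq,cdrb_seq The two sequences.
#' @param pep_xyz,cdrb_xyz Numeric matrices of representative-atom
#'   coordinates, one row per residue, three columns (x, y, z), in the
#'   order of the sequences. Rows with any `NA` coordinate are an error
#'   naming the residue.
#' @return A `distance_map`.
#' @export
#' @examples
#' distance_map_from_coords("toy", "AC", "DEF",
#'   pep_xyz = rbind(c(0, 0, 0), c(1, 0, 0)),
#'   cdrb_xyz = rbind(c(3, 4, 0), c(0, 0, 0), c(1, 1, 1)))
distance_map_from_coords <- function(complex_id, peptide_seq, cdrb_seq,
                                     pep_xyz, cdrb_xyz) {
  pep_xyz <- as.matrix(pep_xyz); cdrb_xyz <- as.matrix(cdrb_xyz)
  check_xyz <- function(xyz, seq, role) {
    if (nrow(xyz) != nchar(seq) || ncol(xyz) != 3L) {
      stop(role, " coordinates must be ", nchar(seq), " x 3", call. = FALSE)
    }
    bad <- which(apply(xyz, 1L, function(r) any(is.na(r))))
    if (length(bad)) {
      stop("missing representative atom for ", role, " residue(s) ",
           paste(bad, collapse = ", "), " (",
           paste(strsplit(seq, "")[[1L]][bad], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  check_xyz(pep_xyz, peptide_seq, "peptide")
  check_xyz(cdrb_xyz, cdrb_seq, "CDRb")
  # ||p - q||^2 = |p|^2 + |q|^2 - 2 p.q, clamped at 0 for roundoff
  cross <- pep_xyz %*% t(cdrb_xyz)
  d2 <- outer(rowSums(pep_xyz^2), rowSums(cdrb_xyz^2), `+`) - 2 * cross
  distance_map(complex_id, peptide_seq, cdrb_seq, sqrt(pmax(d2, 0)))
}

#' Distance map from a PDB structure
#'
#' Extracts representative-atom coordinates for a peptide chain and a TCR
#' beta-chain residue range from a PDB file (via the bio3d package) and
#' builds the pairwise distance map. The representative atom is
#' configurable — published distance analyses rarely state their
#' convention — so `"CA"` (default), `"CB"` (falling back to CA for
#' glycine), or `"min"` (minimum heavy-atom distance) are offered.
#'
#' @param pdb_path Path to a PDB file.
#' @param pep_chain,beta_chain Chain identifiers in the PDB file.
#' @param atom `"CA"`, `"CB"`, or `"min"`.
#' @param beta_resno Optional integer vector restricting the beta chain to
#'   given residue numbers (e.g. a CDR loop); default uses all residues.
#' @return A `distance_map`.
#' @export
distance_map_from_pdb <- function(pdb_path, pep_chain, beta_chain,
                                  atom = c("CA", "CB", "min"),
                                  beta_resno = NULL) {
  atom <- match.arg(atom)
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("distance_map_from_pdb() requires the bio3d package",
         call. = FALSE)
  }
  pdb <- bio3d::read.pdb(pdb_path)
  grab <- function(chain, resno = NULL) {
    sel <- pdb$atom$chain == chain & pdb$atom$type == "ATOM"
    if (!is.null(resno)) sel <- sel & pdb$atom$resno %in% resno
    at <- pdb$atom[sel, , drop = FALSE]
    if (nrow(at) == 0L) stop("no atoms for chain ", chain, call. = FALSE)
    at
  }
  res_seq <- function(at) {
    r <- at[!duplicated(at$resno), , drop = FALSE]
    paste(bio3d::aa321(r$resid), collapse = "")
  }
  rep_xyz <- function(at) {
    resnos <- unique(at$resno)
    t(vapply(resnos, function(rn) {
      a <- at[at$resno == rn, , drop = FALSE]
      pick <- if (atom == "CA") "CA" else "CB"
      row <- a[a$elety == pick, , drop = FALSE]
      if (nrow(row) == 0L && atom == "CB") row <- a[a$elety == "CA", , drop = FALSE]
      if (nrow(row) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      as.numeric(row[1L, c("x", "y", "z")])
    }, numeric(3)))
  }
  pa <- grab(pep_chain)
  ba <- grab(beta_chain, beta_resno)
  pep_seq <- res_seq(pa); beta_seq <- res_seq(ba)
  if (atom == "min") {
    presnos <- unique(pa$resno); bresnos <- unique(ba$resno)
    d <- matrix(NA_real_, length(presnos), length(bresnos))
    for (i in seq_along(presnos)) {
      pi <- as.matrix(pa[pa$resno == presnos[i], c("x", "y", "z")])
      for (j in seq_along(bresnos)) {
        bj <- as.matrix(ba[ba$resno == bresnos[j], c("x", "y", "z")])
        d[i, j] <- sqrt(min(outer(rowSums(pi^2), rowSums(bj^2), `+`) -
                              2 * pi %*% t(bj)))
      }
    }
    distance_map(basename(pdb_path), pep_seq, beta_seq, d)
  } else {
    distance_map_from_coords(basename(pdb_path), pep_seq, beta_seq,
                             rep_xyz(pa), rep_xyz(ba))
  }
}
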