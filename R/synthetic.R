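# Synthetic repertoire generator: peptides with controllable cognate-TCR
# count imbalance, planted peptide-dependent CDR3-beta motifs (the
# learnable signal), cross-reactive TCRs, a compositionally shifted
# negative-control pool, and structure fixtures whose short distances
# coincide with the planted motif positions.

#' Generator configuration
#'
#' Defines the synthetic study conditions. Defaults give the fast-suite
#' fixture (10 peptides x 50 TCRs); the acceptance-scale fixture uses 20
#' peptides x 100 TCRs.
#'
#' @param n_peptides Number of distinct peptides.
#' @param peptide_length Length range (min, max) for peptides.
#' @param tcrs_per_peptide Mean cognate-TCR count per peptide.
#' @param count_distribution `"uniform"` (every peptide gets
#'   `tcrs_per_peptide`) or `"power"` (counts proportional to
#'   rank^-`power_exponent`, emulating the heavy-tailed imbalance of
#'   real databases, rescaled to the same total).
#' @param power_exponent Power-law exponent for `"power"`.
#' @param cdr_length Named list of length ranges per CDR slot.
#' @param motif_strength Probability that a binder carries its peptide's
#'   planted motif.
#' @param motif_length Planted motif length.
#' @param motif_offset 1-based position of the motif within CDR3-beta.
#' @param cross_reactivity_rate Fraction of TCRs duplicated as binders of
#'   a second peptide (with that peptide's motif also planted).
#' @param similarity_link If `TRUE`, motifs are a fixed residue-wise
#'   function of the peptide's first residues, so similar peptides carry
#'   similar motifs, and peptides are generated in mutation families;
#'   if `FALSE` each peptide's motif is drawn independently (private).
#' @param control_pool_size Size of the negative-control TCR pool.
#' @param control_composition_shift Amino-acid frequency bias of the
#'   control pool in \[0, 1\]: 0 reproduces the positive-TCR residue
#'   distribution, larger values mix in a Dirichlet-drawn frequency
#'   perturbation (the control-pool compositional bias knob).
#' @param seed Mandatory integer seed; generation is fully deterministic.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_peptides = 10L, peptide_length = c(9L, 11L),
                             tcrs_per_peptide = 50L,
                             count_distribution = c("uniform", "power"),
                             power_exponent = 1.5,
                             cdr_length = list(A1 = c(5L, 7L),
                                               A2 = c(6L, 8L),
                                               A3 = c(10L, 16L),
                                               B1 = c(5L, 7L),
                                               B2 = c(6L, 8L),
                                               B3 = c(12L, 16L)),
                             motif_strength = 1, motif_length = 3L,
                             motif_offset = 4L,
                             cross_reactivity_rate = 0.05,
                             similarity_link = FALSE,
                             control_pool_size = 500L,
                             control_composition_shift = 0.3,
                             seed) {
  count_distribution <- match.arg(count_distribution)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(motif_strength >= 0, motif_strength <= 1,
            cross_reactivity_rate >= 0, cross_reactivity_rate <= 1,
            control_composition_shift >= 0,
            control_composition_shift <= 1,
            motif_length >= 1, n_peptides >= 1)
  if (motif_offset + 2L * motif_length - 1L > cdr_length$B3[1]) {
    stop("two motifs at offset ", motif_offset,
         " must fit the minimum CDR3-beta length ", cdr_length$B3[1],
         call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

random_seqs <- function(n, len_range) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(aa_alphabet(), l, replace = TRUE), collapse = "")
  }, character(1))
}

# fixed residue-wise substitution used by similarity-linked motifs:
# a seeded-but-frozen permutation of the alphabet
.motif_map <- local({
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  stats::setNames(ab[c(7, 19, 2, 11, 16, 1, 14, 20, 5, 9,
                       18, 3, 12, 17, 6, 10, 4, 15, 8, 13)], ab)
})

#' Generate a synthetic TCR-epitope repertoire
#'
#' Draws peptides, assigns each a planted CDR3-beta motif, and generates
#' cognate TCRs: a `motif_strength` fraction of each peptide's binders
#' carries the peptide's motif at a fixed CDR3-beta offset. A
#' `cross_reactivity_rate` fraction of TCRs is duplicated as a binder of
#' a second peptide with that peptide's motif planted alongside the
#' first. The control pool is drawn with Dirichlet-perturbed residue
#' frequencies. Ground truth (motif table and per-record motif carriage)
#' is returned for test assertions.
#'
#' @param cfg A [generator_config()].
#' @return List with `positives` (dataset tibble, all `binder = 1`,
#'   origin `"synthetic"`), `pool` (control-pool tibble), and `truth`
#'   (list: `motifs` tibble with `peptide`, `motif`, `offset`;
#'   `records` tibble flagging motif carriage per row).
#' @export
generate_repertoire <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    # peptides (mutation families when similarity-linked)
    if (cfg$similarity_link) {
      n_seed <- max(1L, ceiling(cfg$n_peptides / 3))
      seeds <- unique(random_seqs(n_seed, cfg$peptide_length))
      peps <- seeds
      while (length(peps) < cfg$n_peptides) {
        base <- sample(seeds, 1L)
        ch <- strsplit(base, "")[[1L]]
        # mutate one position outside the motif-determining prefix
        pos <- sample((cfg$motif_length + 1L):length(ch), 1L)
        ch[pos] <- sample(aa_alphabet(), 1L)
        cand <- paste(ch, collapse = "")
        if (!cand %in% peps) peps <- c(peps, cand)
      }
    } else {
      peps <- unique(random_seqs(cfg$n_peptides * 2L, cfg$peptide_length))
      while (length(peps) < cfg$n_peptides) {
        peps <- unique(c(peps, random_seqs(cfg$n_peptides,
                                           cfg$peptide_length)))
      }
      peps <- peps[seq_len(cfg$n_peptides)]
    }
    # motif per peptide
    motifs <- if (cfg$similarity_link) {
      vapply(peps, function(p) {
        paste(.motif_map[strsplit(substr(p, 1L, cfg$motif_length),
                                  "")[[1L]]], collapse = "")
      }, character(1))
    } else {
      vapply(peps, function(p) {
        paste(sample(aa_alphabet(), cfg$motif_length, replace = TRUE),
              collapse = "")
      }, character(1))
    }
    # cognate counts
    counts <- if (cfg$count_distribution == "uniform") {
      rep(cfg$tcrs_per_peptide, cfg$n_peptides)
    } else {
      w <- seq_len(cfg$n_peptides)^(-cfg$power_exponent)
      pmax(1L, round(w / sum(w) * cfg$n_peptides * cfg$tcrs_per_peptide))
    }
    # TCRs
    rows <- vector("list", cfg$n_peptides)
    for (i in seq_len(cfg$n_peptides)) {
      n_i <- counts[i]
      tcr <- tibble::tibble(
        peptide = peps[i],
        A1 = random_seqs(n_i, cfg$cdr_length$A1),
        A2 = random_seqs(n_i, cfg$cdr_length$A2),
        A3 = random_seqs(n_i, cfg$cdr_length$A3),
        B1 = random_seqs(n_i, cfg$cdr_length$B1),
        B2 = random_seqs(n_i, cfg$cdr_length$B2),
        B3 = random_seqs(n_i, cfg$cdr_length$B3)
      )
      has_motif <- stats::runif(n_i) < cfg$motif_strength
      if (any(has_motif)) {
        tcr$B3[has_motif] <- plant_motif(tcr$B3[has_motif], motifs[i],
                                         cfg$motif_offset)
      }
      tcr$has_motif <- has_motif
      rows[[i]] <- tcr
    }
    pos <- dplyr::bind_rows(rows)
    pos$motif_start <- ifelse(pos$has_motif, cfg$motif_offset, NA_integer_)
    # cross-reactive duplicates
    n_cross <- round(cfg$cross_reactivity_rate * nrow(pos))
    if (n_cross > 0L && cfg$n_peptides > 1L) {
      pick <- sample.int(nrow(pos), n_cross)
      dup <- pos[pick, , drop = FALSE]
      second <- vapply(dup$peptide, function(p) {
        sample(setdiff(peps, p), 1L)
      }, character(1))
      second <- unname(second)
      m2 <- unname(motifs[match(second, peps)])
      # the shared TCR carries both motifs, at adjacent offsets
      newB3 <- plant_motif(dup$B3, m2, cfg$motif_offset + cfg$motif_length)
      pos$B3[pick] <- newB3
      dup$B3 <- newB3
      dup$peptide <- second
      dup$has_motif <- TRUE
      dup$motif_start <- cfg$motif_offset + cfg$motif_length
      pos <- dplyr::bind_rows(pos, dup)
    }
    # control pool with shifted composition
    base_freq <- rep(1 / 20, 20L)
    pert <- as.numeric(stats::rgamma(20L, shape = 1))
    pert <- pert / sum(pert)
    freq <- (1 - cfg$control_composition_shift) * base_freq +
      cfg$control_composition_shift * pert
    ctrl_seq <- function(n, len_range) {
      lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
      vapply(lens, function(l) {
        paste(sample(aa_alphabet(), l, replace = TRUE, prob = freq),
              collapse = "")
      }, character(1))
    }
    pool <- tibble::tibble(
      A1 = ctrl_seq(cfg$control_pool_size, cfg$cdr_length$A1),
      A2 = ctrl_seq(cfg$control_pool_size, cfg$cdr_length$A2),
      A3 = ctrl_seq(cfg$control_pool_size, cfg$cdr_length$A3),
      B1 = ctrl_seq(cfg$control_pool_size, cfg$cdr_length$B1),
      B2 = ctrl_seq(cfg$control_pool_size, cfg$cdr_length$B2),
      B3 = ctrl_seq(cfg$control_pool_size, cfg$cdr_length$B3)
    )
  })
  truth_records <- tibble::tibble(
    row = seq_len(nrow(pos)), peptide = pos$peptide,
    has_motif = pos$has_motif, motif_start = pos$motif_start)
  positives <- pos[c("peptide", cdr_slots())]
  positives$binder <- 1L
  positives$partition <- NA_integer_
  positives$origin <- "synthetic"
  positives <- validate_tcr_dataset(positives)
  pool <- validate_control_pool(pool)
  list(positives = positives, pool = pool,
       truth = list(motifs = tibble::tibble(peptide = peps, motif = motifs,
                                            offset = cfg$motif_offset),
                    records = truth_records))
}

plant_motif <- function(b3, motif, offset) {
  motif <- rep_len(motif, length(b3))
  mlen <- nchar(motif)
  vapply(seq_along(b3), function(i) {
    s <- b3[i]
    paste0(substr(s, 1L, offset - 1L), motif[i],
           substr(s, offset + mlen[i], nchar(s)))
  }, character(1))
}

#' Generate a synthetic structure fixture
#'
#' Builds a distance map for one (peptide, TCR) pair in which planted
#' contact pairs — every peptide position against the CDR3-beta motif
#' positions, expressed in the concatenated CDR-beta chain frame — are
#' close (distances uniform on `close_range`) and all other pairs are
#' not (uniform on `far_range`). With the default 10 angstrom
#' close-pair rule, planted pairs always classify close and non-planted
#' pairs never do.
#'
#' @param record One-row dataset tibble (the complex's peptide and TCR).
#' @param motif_start Motif start within CDR3-beta (from the generator's
#'   ground truth).
#' @param motif_length Motif length.
#' @param complex_id Identifier for the fixture.
#' @param close_range,far_range Distance ranges in angstroms.
#' @param seed Integer seed.
#' @return A `distance_map` over peptide x concatenated CDR-beta chain.
#' @export
generate_structure_fixture <- function(record, motif_start,
                                       motif_length = 3L,
                                       complex_id = "synthetic",
                                       close_range = c(4, 9),
                                       far_range = c(12, 40), seed) {
  stopifnot(nrow(record) == 1L)
  cdrb <- paste0(record$B1, record$B2, record$B3)
  np <- nchar(record$peptide); nb <- nchar(cdrb)
  motif_cols <- nchar(record$B1) + nchar(record$B2) + motif_start - 1L +
    seq_len(motif_length)
  d <- withr::with_seed(seed, {
    m <- matrix(stats::runif(np * nb, far_range[1], far_range[2]), np, nb)
    m[, motif_cols] <- stats::runif(np * motif_length, close_range[1],
                                    close_range[2])
    m
  })
  dm <- distance_map(complex_id, record$peptide, cdrb, d)
  attr(dm, "planted_cols") <- motif_cols
  dm
}
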