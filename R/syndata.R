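#' Synthetic data generators
#'
#' Everything the pipeline consumes can be generated here with recorded
#' ground truth: population expression profiles, single cells, pseudobulk
#' mixtures, targeted reads carrying fusion junctions, and survival
#' outcomes driven by a stemness covariate. All generators are pure
#' functions of their arguments and `seed`.
#'
#' @name syndata
NULL

#' Default population names
#'
#' The nine bone-marrow populations used throughout: six APL blast
#' branches (stem-like, Prog-like, GMP-like, cycling GMP-like,
#' S100hiGMP-like, MDP-like) and three non-leukemic types (T/NK, B,
#' erythroid).
#'
#' @return Character vector of length 9.
#' @export
apl_populations <- function() {
  c("stem-like", "Prog-like", "GMP-like", "cycling GMP-like",
    "S100hiGMP-like", "MDP-like", "T/NK", "B", "erythroid")
}

#' Build population expression profiles
#'
#' Constructs a genes-by-populations matrix of expected expression on a
#' linear scale. Each population receives a disjoint set of marker genes
#' elevated `effect_size`-fold over a common baseline; all other genes sit
#' at the baseline with mild lognormal gene-to-gene variation shared
#' across populations. A block of mitochondrial genes (named with an
#' `MT-` prefix) is reserved so the downstream QC mito rule is exercised
#' through gene names, matching droplet-pipeline convention.
#'
#' @param n_genes Total number of genes (including mito genes).
#' @param populations Character vector of population names.
#' @param markers_per_pop Number of marker genes per population.
#' @param effect_size Fold elevation of a marker over baseline (> 1).
#' @param baseline_mean Baseline expected expression (> 0).
#' @param n_mito_genes Genes given the `MT-` prefix (never markers).
#' @param gene_noise_sd Lognormal sd of shared per-gene baseline wobble.
#' @param seed Integer seed.
#'
#' @return A `pop_profiles` object: list with `gene_ids`, `populations`,
#'   `mean_matrix` (genes x populations), `marker_map` (named list of
#'   marker gene ids), `effect_size`, `baseline_mean`.
#' @export
make_population_profiles <- function(n_genes = 2000,
                                     populations = apl_populations(),
                                     markers_per_pop = 40,
                                     effect_size = 8,
                                     baseline_mean = 1,
                                     n_mito_genes = 10,
                                     gene_noise_sd = 0.2,
                                     seed = 1L) {
  n_pop <- length(populations)
  if (effect_size <= 1) abort("`effect_size` must be > 1.")
  if (baseline_mean <= 0) abort("`baseline_mean` must be positive.")
  if (n_genes < n_pop * markers_per_pop + n_mito_genes) {
    abort(sprintf(
      "too few genes: %d populations x %d markers (+%d mito) need > %d genes.",
      n_pop, markers_per_pop, n_mito_genes, n_pop * markers_per_pop + n_mito_genes))
  }
  withr::with_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    if (n_mito_genes > 0) {
      gene_ids[seq_len(n_mito_genes)] <- sprintf("MT-%02d", seq_len(n_mito_genes))
    }
    # shared baseline with per-gene wobble, identical across populations
    base <- baseline_mean * exp(rnorm(n_genes, 0, gene_noise_sd))
    mean_matrix <- matrix(rep(base, n_pop), nrow = n_genes,
                          dimnames = list(gene_ids, populations))
    eligible <- setdiff(seq_len(n_genes), seq_len(n_mito_genes))
    marker_idx <- matrix(sample(eligible, n_pop * markers_per_pop),
                         nrow = markers_per_pop)
    marker_map <- setNames(vector("list", n_pop), populations)
    for (j in seq_len(n_pop)) {
      idx <- marker_idx[, j]
      mean_matrix[idx, j] <- mean_matrix[idx, j] * effect_size
      marker_map[[j]] <- gene_ids[idx]
    }
    structure(list(gene_ids = gene_ids, populations = populations,
                   mean_matrix = mean_matrix, marker_map = marker_map,
                   effect_size = effect_size, baseline_mean = baseline_mean,
                   n_mito_genes = n_mito_genes, seed = seed),
              class = "pop_profiles")
  })
}

#' @export
print.pop_profiles <- function(x, ...) {
  cat(sprintf("<pop_profiles> %d genes, %d populations, %d markers each (%.3gx)\n",
              length(x$gene_ids), length(x$populations),
              length(x$marker_map[[1]]), x$effect_size))
  invisible(x)
}

#' Simulate single cells from population profiles
#'
#' Counts are drawn from a negative-binomial model with a shared
#' dispersion: for a cell of population p, per-gene means are the
#' population profile rescaled so non-mitochondrial genes carry
#' `(1 - f) * library_size` expected counts and the reserved `MT-` genes
#' carry `f * library_size`, with the cell's mitochondrial share f drawn
#' from a Beta distribution.
#'
#' @param profiles A [make_population_profiles()] object.
#' @param cells_per_pop Named integer vector: cells to draw per population
#'   (names must be populations in `profiles`); an unnamed scalar is
#'   recycled to all populations.
#' @param library_size Target expected total counts per cell.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   must be > 0.
#' @param mito_shape Beta shape parameters (length 2) for the per-cell
#'   mitochondrial fraction; default mean 5%.
#' @param sample_id Sample id recorded in cell metadata.
#' @param barcode_prefix Prefix for generated barcodes.
#' @param seed Integer seed.
#'
#' @return A list with `matrix` (a [gexp] whose `cell_meta` carries the
#'   true `label`) and `truth` (tibble barcode, label).
#' @export
simulate_cells <- function(profiles, cells_per_pop, library_size = 5000,
                           dispersion = 0.3, mito_shape = c(2, 38),
                           sample_id = "S1", barcode_prefix = "BC",
                           seed = 1L) {
  stopifnot(inherits(profiles, "pop_profiles"))
  if (library_size <= 0) abort("`library_size` must be positive.")
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  pops <- profiles$populations
  if (length(cells_per_pop) == 1 && is.null(names(cells_per_pop))) {
    cells_per_pop <- setNames(rep(cells_per_pop, length(pops)), pops)
  }
  if (is.null(names(cells_per_pop))) {
    abort("`cells_per_pop` must be named by population (or be a scalar).")
  }
  if (!all(names(cells_per_pop) %in% pops)) {
    abort("names of `cells_per_pop` must be populations of `profiles`.")
  }
  if (any(cells_per_pop < 1)) abort("`cells_per_pop` must be >= 1 per population.")

  n_mito <- profiles$n_mito_genes
  mito_idx <- seq_len(n_mito)
  withr::with_seed(seed, {
    n_cells <- sum(cells_per_pop)
    labels <- rep(names(cells_per_pop), cells_per_pop)
    barcodes <- sprintf("%s-%s-%06d", barcode_prefix, sample_id, seq_len(n_cells))
    size <- 1 / dispersion
    cols <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      mu <- profiles$mean_matrix[, labels[i]]
      f <- if (n_mito > 0) rbeta(1, mito_shape[1], mito_shape[2]) else 0
      if (n_mito > 0) {
        mu_m <- mu[mito_idx]; mu_r <- mu[-mito_idx]
        mu[mito_idx] <- mu_m / sum(mu_m) * f * library_size
        mu[-mito_idx] <- mu_r / sum(mu_r) * (1 - f) * library_size
      } else {
        mu <- mu / sum(mu) * library_size
      }
      cols[[i]] <- rnbinom(length(mu), size = size, mu = mu)
    }
    counts <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
    dimnames(counts) <- list(profiles$gene_ids, barcodes)
    meta <- tibble(barcode = barcodes, sample_id = sample_id, label = labels)
    list(matrix = gexp(counts, meta), truth = tibble(barcode = barcodes, label = labels))
  })
}

#' Simulate pseudobulk mixtures with known proportions
#'
#' Two modes. `"expectation"` mixes the population expected profiles
#' (each first rescaled to counts-per-million so mixing weights are cell
#' proportions at equal depth), giving an analytic ground truth;
#' `"resample"` sums negative-binomial cells drawn per population, giving
#' a sampling-noise ground truth. Multiplicative lognormal jitter with sd
#' `noise_sd` (log scale) is applied per gene per sample before the final
#' CPM rescale.
#'
#' @param profiles A [make_population_profiles()] object.
#' @param proportions Numeric matrix or data frame, samples x populations;
#'   rows must be non-negative and sum to 1. Rownames are sample ids.
#' @param noise_sd Sd of per-gene lognormal jitter on the natural-log scale.
#' @param mode `"expectation"` or `"resample"`.
#' @param cells_per_sample Cells drawn per sample in `"resample"` mode.
#' @param library_size,dispersion Passed to the cell sampler in
#'   `"resample"` mode.
#' @param seed Integer seed.
#'
#' @return List with `bulk` (genes x samples matrix on a CPM/TPM-like
#'   scale) and `truth` (tibble sample_id, population, proportion).
#' @export
simulate_pseudobulk <- function(profiles, proportions, noise_sd = 0,
                                mode = c("expectation", "resample"),
                                cells_per_sample = 500, library_size = 5000,
                                dispersion = 0.3, seed = 1L) {
  stopifnot(inherits(profiles, "pop_profiles"))
  mode <- match.arg(mode)
  P <- as.matrix(proportions)
  if (is.null(rownames(P))) rownames(P) <- sprintf("PB%02d", seq_len(nrow(P)))
  if (is.null(colnames(P))) colnames(P) <- profiles$populations
  if (any(P < 0)) abort("proportions must be non-negative.")
  if (any(abs(rowSums(P) - 1) > 1e-9)) abort("each proportions row must sum to 1.")
  if (!all(colnames(P) %in% profiles$populations)) {
    abort("proportion columns must be populations of `profiles`.")
  }
  prof_cpm <- sweep(profiles$mean_matrix[, colnames(P), drop = FALSE], 2,
                    colSums(profiles$mean_matrix[, colnames(P), drop = FALSE]),
                    "/") * 1e6
  withr::with_seed(seed, {
    bulk <- matrix(0, nrow = length(profiles$gene_ids), ncol = nrow(P),
                   dimnames = list(profiles$gene_ids, rownames(P)))
    for (s in seq_len(nrow(P))) {
      if (mode == "expectation") {
        v <- as.numeric(prof_cpm %*% P[s, ])
      } else {
        n_per <- as.integer(rmultinom(1, cells_per_sample, P[s, ]))
        names(n_per) <- colnames(P)
        n_per <- n_per[n_per > 0]
        cells <- simulate_cells(profiles, n_per, library_size = library_size,
                                dispersion = dispersion,
                                sample_id = rownames(P)[s],
                                seed = sample.int(.Machine$integer.max, 1))
        v <- as.numeric(Matrix::rowSums(cells$matrix$counts))
      }
      if (noise_sd > 0) v <- v * exp(rnorm(length(v), 0, noise_sd))
      bulk[, s] <- v / sum(v) * 1e6
    }
    truth <- as_tibble(as.data.frame.table(P, stringsAsFactors = FALSE))
    names(truth) <- c("sample_id", "population", "proportion")
    list(bulk = bulk, truth = truth)
  })
}

#' Junction specification for fusion / ITD k-mer detection
#'
#' Derives the breakpoint-spanning k-mer from the two flanks: the last
#' `ceiling(k/2)` bases of the upstream flank joined to the first
#' `floor(k/2)` bases of the downstream flank (odd k takes the extra base
#' upstream).
#'
#' @param upstream_flank,downstream_flank Nucleotide strings (A/C/G/T/N)
#'   ending at / starting from the breakpoint.
#' @param k K-mer length (default 12).
#' @param name Junction name, e.g. `"PML-RARA-L"` or `"FLT3-ITD"`.
#'
#' @return A `junction_spec` list with `name`, flanks, `k`, `junction_kmer`.
#' @export
build_junction_kmer <- function(upstream_flank, downstream_flank, k = 12,
                                name = "junction") {
  up <- toupper(upstream_flank); down <- toupper(downstream_flank)
  if (grepl("[^ACGTN]", up) || grepl("[^ACGTN]", down)) {
    abort("flanks may contain only A, C, G, T, N.")
  }
  n_up <- ceiling(k / 2); n_down <- k - n_up
  if (nchar(up) < n_up) abort(sprintf("upstream flank shorter than %d bases.", n_up))
  if (nchar(down) < n_down) abort(sprintf("downstream flank shorter than %d bases.", n_down))
  kmer <- paste0(substr(up, nchar(up) - n_up + 1, nchar(up)),
                 substr(down, 1, n_down))
  structure(list(name = name, upstream_flank = up, downstream_flank = down,
                 k = as.integer(k), junction_kmer = kmer),
            class = "junction_spec")
}

#' @export
print.junction_spec <- function(x, ...) {
  cat(sprintf("<junction_spec> %s: %s (k=%d)\n", x$name, x$junction_kmer, x$k))
  invisible(x)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

contains_any_kmer <- function(seqs, kmers) {
  hit <- rep(FALSE, length(seqs))
  for (km in kmers) {
    hit <- hit | stringr::str_detect(seqs, stringr::fixed(km)) |
      stringr::str_detect(seqs, stringr::fixed(revcomp(km)))
  }
  hit
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate targeted reads with planted fusion junctions
#'
#' Positive cells receive reads that contain the full junction k-mer at a
#' random offset, embedded in the junction's flank context (extended with
#' random bases where a flank is shorter than the read); background reads
#' are built from wild-type flank sequence only and are rejection-sampled
#' to guarantee they contain no junction k-mer on either strand. Cell
#' barcode and UMI are encoded in the read name as
#' `..._CB:<barcode>_UMI:<umi>`.
#'
#' @param junctions List of [build_junction_kmer()] specs.
#' @param cell_barcodes Character vector of all cell barcodes.
#' @param positive_cells Named list (per junction name) of named integer
#'   vectors barcode -> planted read count; or, with one junction, a
#'   single named integer vector.
#' @param background_reads_per_cell Wild-type reads per cell.
#' @param read_length Read length in bases (> k of every junction).
#' @param error_rate Per-base substitution probability applied to every
#'   read after construction.
#' @param unique_umis If `FALSE`, UMIs are drawn with replacement from a
#'   small pool so deduplication has something to do.
#' @param seed Integer seed.
#'
#' @return List with `reads` (tibble read_id, sequence, barcode, umi) and
#'   `truth` (tibble barcode, junction, planted_reads).
#' @export
simulate_targeted_reads <- function(junctions, cell_barcodes, positive_cells,
                                    background_reads_per_cell = 2,
                                    read_length = 60, error_rate = 0,
                                    unique_umis = TRUE, seed = 1L) {
  if (inherits(junctions, "junction_spec")) junctions <- list(junctions)
  jnames <- map_chr(junctions, "name")
  names(junctions) <- jnames
  if (is.numeric(positive_cells)) {
    positive_cells <- setNames(list(positive_cells), jnames[1])
  }
  if (!all(names(positive_cells) %in% jnames)) {
    abort("names of `positive_cells` must be junction names.")
  }
  for (jn in names(positive_cells)) {
    if (!all(names(positive_cells[[jn]]) %in% cell_barcodes)) {
      abort("every positive barcode must be in `cell_barcodes`.")
    }
  }
  kmax <- max(map_dbl(junctions, "k"))
  if (read_length <= kmax) abort("`read_length` must exceed the junction k-mer length.")
  all_kmers <- map_chr(junctions, "junction_kmer")

  withr::with_seed(seed, {
    umi_pool <- if (unique_umis) NULL else
      vapply(seq_len(16), function(i) random_bases(10), "")
    rows <- list(); ridx <- 0L
    next_umi <- local({
      counter <- 0L
      function() {
        counter <<- counter + 1L
        if (unique_umis) sprintf("UMI%08d", counter) else sample(umi_pool, 1)
      }
    })
    plant_read <- function(spec) {
      k <- spec$k
      offset <- sample.int(read_length - k + 1, 1)  # 1-based start of kmer
      left_need <- offset - 1
      right_need <- read_length - k - left_need
      up_extra <- substr(spec$upstream_flank, 1,
                         nchar(spec$upstream_flank) - ceiling(k / 2))
      down_extra <- substr(spec$downstream_flank, k - ceiling(k / 2) + 1,
                           nchar(spec$downstream_flank))
      left <- if (left_need <= nchar(up_extra)) {
        substr(up_extra, nchar(up_extra) - left_need + 1, nchar(up_extra))
      } else {
        paste0(random_bases(left_need - nchar(up_extra)), up_extra)
      }
      right <- if (right_need <= nchar(down_extra)) {
        substr(down_extra, 1, right_need)
      } else {
        paste0(down_extra, random_bases(right_need - nchar(down_extra)))
      }
      paste0(left, spec$junction_kmer, right)
    }
    background_read <- function() {
      repeat {
        # wild-type context: one flank extended with random sequence
        spec <- junctions[[sample.int(length(junctions), 1)]]
        flank <- if (runif(1) < 0.5) spec$upstream_flank else spec$downstream_flank
        s <- if (nchar(flank) >= read_length) {
          start <- sample.int(nchar(flank) - read_length + 1, 1)
          substr(s <- flank, start, start + read_length - 1)
        } else {
          paste0(flank, random_bases(read_length - nchar(flank)))
        }
        if (!contains_any_kmer(s, all_kmers)) return(s)
      }
    }
    add_read <- function(seq, bc) {
      ridx <<- ridx + 1L
      rows[[ridx]] <<- tibble(read_id = sprintf("read%07d", ridx),
                              sequence = seq, barcode = bc, umi = next_umi())
    }
    for (bc in cell_barcodes) {
      for (jn in names(positive_cells)) {
        n_pos <- positive_cells[[jn]][bc]
        if (!is.na(n_pos) && n_pos > 0) {
          for (i in seq_len(n_pos)) add_read(plant_read(junctions[[jn]]), bc)
        }
      }
      if (background_reads_per_cell > 0) {
        for (i in seq_len(background_reads_per_cell)) add_read(background_read(), bc)
      }
    }
    reads <- bind_rows(rows)
    if (error_rate > 0) {
      reads$sequence <- vapply(reads$sequence, function(s) {
        b <- strsplit(s, "")[[1]]
        flip <- runif(length(b)) < error_rate
        if (any(flip)) b[flip] <- vapply(b[flip], function(orig) {
          sample(setdiff(c("A", "C", "G", "T"), orig), 1)
        }, "")
        paste(b, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    truth <- bind_rows(imap(positive_cells, function(v, jn) {
      tibble(barcode = names(v), junction = jn, planted_reads = as.integer(v))
    }))
    # cells with no plants are implicit zeros; record them for completeness
    truth <- tidyr::complete(truth,
                             barcode = cell_barcodes,
                             junction = names(positive_cells),
                             fill = list(planted_reads = 0L))
    list(reads = reads, truth = truth)
  })
}

#' Simulate survival outcomes driven by a score
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(effect_beta * score)`. A fraction `censor_rate`
#' of subjects is independently censored at a uniform time before their
#' event; follow-up is administratively truncated at `max_follow_up`.
#'
#' @param scores Named numeric vector (names are sample ids) or tibble
#'   with columns `sample_id`, `score`.
#' @param effect_beta Log-hazard increase per unit score.
#' @param baseline_rate Baseline hazard (events per unit time, > 0).
#' @param censor_rate Fraction of subjects censored (in `[0, 1)`).
#' @param max_follow_up Administrative censoring time.
#' @param seed Integer seed.
#'
#' @return Tibble: sample_id, time, event (1 = event, 0 = censored), score.
#' @export
simulate_survival <- function(scores, effect_beta = 1, baseline_rate = 0.1,
                              censor_rate = 0.1, max_follow_up = Inf,
                              seed = 1L) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$sample_id)
  }
  if (length(scores) == 0) abort("`scores` is empty.")
  if (baseline_rate <= 0) abort("`baseline_rate` must be > 0.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1).")
  ids <- names(scores) %||% sprintf("S%03d", seq_along(scores))
  withr::with_seed(seed, {
    haz <- baseline_rate * exp(effect_beta * scores)
    t_event <- rexp(length(scores), rate = haz)
    event <- rep(1L, length(scores))
    time <- t_event
    cens <- runif(length(scores)) < censor_rate
    time[cens] <- runif(sum(cens), 0, t_event[cens])
    event[cens] <- 0L
    over <- time > max_follow_up
    time[over] <- max_follow_up
    event[over] <- 0L
    tibble(sample_id = ids, time = time, event = event,
           score = unname(scores))
  })
}
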