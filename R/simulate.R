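#' Simulation configuration for a two-context pooled screen
#'
#' Bundles the design and effect-size parameters of the synthetic screen
#' generator. Defaults describe a targeted dropout screen: 1000 genes with
#' 3 guides each, samples taken every 3 days from day 0 to day 18 in 3
#' replicates per genotype context, multinomial sequencing at an expected
#' 500 reads per guide. Fitness is parameterized in log2 units per day, so
#' a gene with fitness \eqn{\phi} changes its relative abundance by
#' \eqn{2^{\phi t}} over \eqn{t} days.
#'
#' @param n_genes Number of genes (default 1000).
#' @param guides_per_gene Guides per gene (default 3).
#' @param timepoints_days Sampled timepoints in days; must include 0
#'   (default \code{seq(0, 18, 3)}).
#' @param n_replicates Replicates per context (default 3).
#' @param depth_per_guide Expected reads per guide per sample; the total
#'   multinomial depth is \code{round(depth_per_guide * n_guides)}
#'   (default 500).
#' @param doublings_per_day Population doublings per day, recorded for
#'   provenance; relative-abundance dynamics do not depend on it
#'   (default 0.8).
#' @param fraction_essential Fraction of genes that are essential
#'   (default 0.1).
#' @param essential_fitness Fitness of essential-gene knockouts in both
#'   contexts, log2 units/day (default -0.25, i.e. -4.5 log2 units over an
#'   18-day screen).
#' @param base_fitness_sd SD of per-gene background fitness shared by both
#'   contexts, log2/day (default 0.05): knockouts have heterogeneous
#'   fitness even when not essential.
#' @param n_positive_gi,n_negative_gi Number of genes given a true
#'   positive / negative genetic interaction (defaults 50 and 50).
#' @param gi_effect Magnitude of the true interaction, log2 units/day
#'   (default 1.5/18: a 1.5 log2-unit differential at the day-18 endpoint).
#' @param background_gi_sd SD of per-gene context-specific fitness jitter,
#'   log2/day, applied to every gene (default 0.15/18): knockout effects
#'   are never perfectly identical across genotype backgrounds.
#' @param guide_effect_sd SD of per-guide fitness deviation (guide
#'   efficiency), shared across contexts, log2/day (default 0.02).
#' @param t0_abundance_log_sd Lognormal sdlog of starting guide abundances
#'   (default 0.5).
#' @param ma_bias_slope Optional abundance-dependent bias injected into the
#'   mutant context: each guide's mutant abundance at time t is multiplied
#'   by \code{2^(ma_bias_slope * A_hat)} with \code{A_hat} the guide's
#'   expected mean LFC at t. Default 0 (no bias); nonzero values exercise
#'   the MA/loess normalization.
#' @param moi,library_representation Screen-setup parameters recorded for
#'   provenance only (defaults 0.2 and 1000).
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 1000, guides_per_gene = 3,
                       timepoints_days = seq(0, 18, by = 3),
                       n_replicates = 3, depth_per_guide = 500,
                       doublings_per_day = 0.8,
                       fraction_essential = 0.1,
                       essential_fitness = -0.25,
                       base_fitness_sd = 0.05,
                       n_positive_gi = 50, n_negative_gi = 50,
                       gi_effect = 1.5 / 18,
                       background_gi_sd = 0.15 / 18,
                       guide_effect_sd = 0.02,
                       t0_abundance_log_sd = 0.5,
                       ma_bias_slope = 0,
                       moi = 0.2, library_representation = 1000,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, guides_per_gene = guides_per_gene,
              timepoints_days = as.integer(timepoints_days),
              n_replicates = n_replicates,
              depth_per_guide = depth_per_guide,
              doublings_per_day = doublings_per_day,
              fraction_essential = fraction_essential,
              essential_fitness = essential_fitness,
              base_fitness_sd = base_fitness_sd,
              n_positive_gi = n_positive_gi,
              n_negative_gi = n_negative_gi,
              gi_effect = gi_effect,
              background_gi_sd = background_gi_sd,
              guide_effect_sd = guide_effect_sd,
              t0_abundance_log_sd = t0_abundance_log_sd,
              ma_bias_slope = ma_bias_slope,
              moi = moi, library_representation = library_representation,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, cfg$guides_per_gene >= 1,
            0L %in% cfg$timepoints_days, cfg$n_replicates >= 1,
            cfg$fraction_essential >= 0, cfg$fraction_essential <= 1,
            cfg$n_positive_gi + cfg$n_negative_gi +
              round(cfg$fraction_essential * cfg$n_genes) <= cfg$n_genes)
  if (cfg$depth_per_guide <= 0) stop("sequencing depth must be positive",
                                     call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a guide library
#'
#' @param n_genes Number of genes.
#' @param guides_per_gene Guides per gene.
#' @param seed RNG seed (default 1); the caller's RNG state is restored on
#'   exit.
#' @param sequence_length Length of the synthetic protospacers (default 20).
#' @return A \code{guide_library} with unique random sequences.
#' @export
simulate_library <- function(n_genes = 1000, guides_per_gene = 3, seed = 1,
                             sequence_length = 20) {
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    guide_id <- as.vector(t(outer(genes, seq_len(guides_per_gene),
                                  function(g, i) sprintf("%s_g%d", g, i))))
    n <- n_genes * guides_per_gene
    seqs <- random_dna(n, sequence_length)
    while (anyDuplicated(seqs)) {
      dup <- duplicated(seqs)
      seqs[dup] <- random_dna(sum(dup), sequence_length)
    }
    validate_guide_library(data.frame(
      guide_id = guide_id,
      gene_id = rep(genes, each = guides_per_gene),
      sequence = seqs,
      stringsAsFactors = FALSE))
  })
}

#' Simulate a two-context pooled dropout screen
#'
#' Generates raw sgRNA counts for both genotype contexts across all
#' configured timepoints and replicates. Gene categories (essential,
#' positive/negative interactor, null) are assigned at random; each guide's
#' relative abundance follows \eqn{a_g(t) \propto a_g(0) 2^{\phi_g t}} with
#' \eqn{\phi_g} the gene fitness in that context plus a guide-specific
#' deviation shared across contexts; starting abundances are lognormal;
#' sequencing draws each sample's counts from a multinomial at the
#' configured total depth, so replicates differ only by independent
#' sampling.
#'
#' @param library A \code{guide_library} (e.g. from [simulate_library()]);
#'   must have \code{n_genes * guides_per_gene} rows matching the config.
#' @param config A \code{sim_config}.
#' @param truth Optional ground-truth data frame from a previous call, to
#'   simulate an independent replicate experiment with the same underlying
#'   gene effects (new guide deviations, abundances and sampling are
#'   drawn).
#' @return List with \code{counts} (integer matrix), \code{samples}
#'   (a \code{sample_sheet}), and \code{truth}: per-gene \code{category},
#'   \code{fitness_control}, \code{fitness_mutant} (log2/day) and
#'   \code{expected_gi} (log2 units at the last timepoint).
#' @export
simulate_screen <- function(library, config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth_per_guide <= 0) stop("depth of 0", call. = FALSE)
  genes <- unique(library$gene_id)
  n_genes <- length(genes)
  n_guides <- nrow(library)
  endpoint <- max(config$timepoints_days)
  with_seed(config$seed, {
    if (is.null(truth)) {
      n_ess <- round(config$fraction_essential * n_genes)
      category <- rep("null", n_genes)
      pool <- sample.int(n_genes)
      category[pool[seq_len(n_ess)]] <- "essential"
      off <- n_ess
      category[pool[off + seq_len(config$n_positive_gi)]] <- "positive_gi"
      off <- off + config$n_positive_gi
      category[pool[off + seq_len(config$n_negative_gi)]] <- "negative_gi"
      base <- stats::rnorm(n_genes, 0, config$base_fitness_sd)
      base[category == "essential"] <- base[category == "essential"] +
        config$essential_fitness
      gi <- stats::rnorm(n_genes, 0, config$background_gi_sd)
      gi[category == "positive_gi"] <- gi[category == "positive_gi"] +
        config$gi_effect
      gi[category == "negative_gi"] <- gi[category == "negative_gi"] -
        config$gi_effect
      truth <- data.frame(gene_id = genes, category = category,
                          fitness_control = base,
                          fitness_mutant = base + gi,
                          stringsAsFactors = FALSE)
      truth$expected_gi <-
        (truth$fitness_mutant - truth$fitness_control) * endpoint
    } else {
      stopifnot(setequal(truth$gene_id, genes))
      truth <- truth[match(genes, truth$gene_id), , drop = FALSE]
    }
    gidx <- match(library$gene_id, truth$gene_id)
    eps <- stats::rnorm(n_guides, 0, config$guide_effect_sd)
    phi_ctrl <- truth$fitness_control[gidx] + eps
    phi_mut <- truth$fitness_mutant[gidx] + eps
    a0 <- stats::rlnorm(n_guides, 0, config$t0_abundance_log_sd)
    depth <- round(config$depth_per_guide * n_guides)
    contexts <- c("control", "mutant")
    reps <- LETTERS[seq_len(config$n_replicates)]
    n_samples <- length(contexts) * length(config$timepoints_days) *
      length(reps)
    counts <- matrix(0L, nrow = n_guides, ncol = n_samples,
                     dimnames = list(library$guide_id, NULL))
    sheet <- data.frame(sample_id = character(n_samples),
                        context = character(n_samples),
                        timepoint_days = integer(n_samples),
                        replicate = character(n_samples),
                        stringsAsFactors = FALSE)
    j <- 0L
    for (ctx in contexts) {
      phi <- if (ctx == "control") phi_ctrl else phi_mut
      for (t in config$timepoints_days) {
        w <- a0 * 2^(phi * t)
        if (ctx == "mutant" && config$ma_bias_slope != 0) {
          a_hat <- ((phi_mut + phi_ctrl) / 2) * t
          w <- w * 2^(config$ma_bias_slope * a_hat)
        }
        prob <- w / sum(w)
        for (r in reps) {
          j <- j + 1L
          counts[, j] <- stats::rmultinom(1L, size = depth, prob = prob)[, 1L]
          sheet$sample_id[j] <- sprintf("%s_T%02d_%s", ctx, t, r)
          sheet$context[j] <- ctx
          sheet$timepoint_days[j] <- t
          sheet$replicate[j] <- r
        }
      }
    }
    colnames(counts) <- sheet$sample_id
    list(counts = counts, samples = validate_sample_sheet(sheet),
         truth = truth)
  })
}

#' Simulate a gene-set annotation fixture
#'
#' Builds random gene sets over the library, with a configurable number of
#' "enriched" terms whose members are drawn preferentially from genes of a
#' chosen ground-truth category, so their true mean GI differs from the
#' background.
#'
#' @param library A \code{guide_library}.
#' @param truth Ground-truth data frame from [simulate_screen()].
#' @param n_terms Number of terms (default 50).
#' @param size_range Integer range of term sizes (default \code{c(3, 20)}).
#' @param n_enriched Number of enriched terms (default 5).
#' @param enriched_category Ground-truth category enriched terms draw 80%
#'   of their members from (default \code{"negative_gi"}).
#' @param seed RNG seed (default 1).
#' @return List with \code{annotations} (data frame \code{term_id},
#'   \code{gene_id}, \code{term_name}) and \code{term_truth} (data frame
#'   \code{term_id}, \code{enriched}).
#' @export
simulate_annotations <- function(library, truth, n_terms = 50,
                                 size_range = c(3, 20), n_enriched = 5,
                                 enriched_category = "negative_gi",
                                 seed = 1) {
  genes <- unique(library$gene_id)
  stopifnot(size_range[1] >= 1, size_range[2] <= length(genes),
            n_enriched <= n_terms)
  with_seed(seed, {
    term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
    enriched <- seq_len(n_terms) <= n_enriched
    cat_genes <- truth$gene_id[truth$category == enriched_category]
    rows <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      size <- sample(seq(size_range[1], size_range[2]), 1L)
      if (enriched[i] && length(cat_genes) > 0L) {
        n_cat <- min(length(cat_genes), max(1L, round(0.8 * size)))
        mem <- c(sample(cat_genes, n_cat),
                 sample(setdiff(genes, cat_genes), size - n_cat))
      } else {
        mem <- sample(genes, size)
      }
      rows[[i]] <- data.frame(term_id = term_ids[i], gene_id = mem,
                              term_name = sprintf("synthetic term %d", i),
                              stringsAsFactors = FALSE)
    }
    list(annotations = do.call(rbind, rows),
         term_truth = data.frame(term_id = term_ids, enriched = enriched,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate FASTQ reads for a guide library
#'
#' Draws reads from the given guides (each read embeds the guide sequence
#' in random flanking bases), for testing the exact-match counter.
#'
#' @param library A \code{guide_library} with sequences.
#' @param n_reads Integer vector: reads to emit per guide (recycled along
#'   the library, or a named vector of guide ids).
#' @param path Output FASTQ path.
#' @param read_length Total read length (default 50).
#' @param seed RNG seed (default 1).
#' @return Invisibly, \code{path}.
#' @export
simulate_fastq <- function(library, n_reads, path, read_length = 50,
                           seed = 1) {
  stopifnot(!is.null(library$sequence))
  if (!is.null(names(n_reads))) {
    n_reads <- n_reads[library$guide_id]
    n_reads[is.na(n_reads)] <- 0L
  } else {
    n_reads <- rep_len(n_reads, nrow(library))
  }
  with_seed(seed, {
    lines <- character(0)
    idx <- 0L
    for (i in seq_len(nrow(library))) {
      gs <- library$sequence[i]
      pad <- read_length - nchar(gs)
      for (k in seq_len(n_reads[i])) {
        idx <- idx + 1L
        left <- sample.int(max(pad, 0L) + 1L, 1L) - 1L
        read <- paste0(random_dna(1L, left), gs,
                       random_dna(1L, pad - left))
        lines <- c(lines, sprintf("@read%06d", idx), read, "+",
                   strrep("I", nchar(read)))
      }
    }
    writeLines(lines, path)
  })
  invisible(path)
}

#' Write all simulator outputs to a directory
#'
#' @param sim Output of [simulate_screen()].
#' @param library The \code{guide_library} used.
#' @param outdir Output directory (created if missing).
#' @param annotations Optional annotation list from
#'   [simulate_annotations()].
#' @return Invisibly, the directory path.
#' @export
write_simulation <- function(sim, library, outdir, annotations = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(sim$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(library), file.path(outdir, "library.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_results(sim$truth, file.path(outdir, "truth.tsv"))
  writeLines(sim$truth$gene_id[sim$truth$category == "essential"],
             file.path(outdir, "essential_genes.txt"))
  if (!is.null(annotations)) {
    utils::write.table(annotations$annotations,
                       file.path(outdir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

# Evaluate expr with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, len) {
  if (len <= 0L) return(rep("", n))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}
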