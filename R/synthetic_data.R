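# ---------------------------------------------------------------------------
# Fully labeled synthetic inputs: proteomes with planted domains, genome
# layouts with tandem arrays / collinear blocks / mobile elements, and
# replicated expression matrices. Every generator is a pure function of
# (config, seed): identical calls give identical output, and the emitted
# truth labels are consistent with the downstream rule modules by
# construction.
# ---------------------------------------------------------------------------

#' Simulate a seed domain alignment
#'
#' Draws a random consensus of length `length` and emits `n_seqs` rows, each
#' consensus residue substituted with probability `divergence` by a uniformly
#' chosen different residue. The result is a gapless seed alignment from
#' which a test profile can be built.
#'
#' @param label alignment label (used for row names).
#' @param length number of columns.
#' @param n_seqs number of rows (>= 2).
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return a [multiple_alignment].
#' @export
simulate_seed_msa <- function(label, length = 60, n_seqs = 12,
                              divergence = 0.15, seed = 1) {
  stopifnot(n_seqs >= 2, divergence >= 0, divergence <= 1)
  with_seed(seed, {
    consensus <- sample(AA_ALPHABET20, length, replace = TRUE)
    rows <- vapply(seq_len(n_seqs), function(i) {
      r <- consensus
      hit <- runif(length) < divergence
      if (any(hit)) {
        r[hit] <- vapply(r[hit], function(a) {
          sample(setdiff(AA_ALPHABET20, a), 1)
        }, "")
      }
      paste(r, collapse = "")
    }, "")
    names(rows) <- sprintf("%s_seed%02d", label, seq_len(n_seqs))
    multiple_alignment(rows)
  })
}

#' Sample one domain instance from a profile
#'
#' Emits the profile consensus, then at each match column substitutes the
#' residue with probability `divergence` by a draw from that column's match
#' emission distribution (so `divergence = 0` returns the consensus exactly,
#' and at `divergence = 1` the expected Hamming distance to the consensus is
#' `sum_k (1 - max match probability of column k)`).
#'
#' @param profile a `profile_hmm`.
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return a protein segment (string of length `profile$L`).
#' @export
sample_domain_instance <- function(profile, divergence, seed) {
  if (is.null(profile$L) || profile$L < 1) stop("empty profile")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  with_seed(seed, {
    chars <- strsplit(profile$consensus, "")[[1]]
    hit <- runif(profile$L) < divergence
    for (k in which(hit)) {
      chars[k] <- sample(AA_ALPHABET20, 1, prob = profile$match_emissions[k, ])
    }
    paste(chars, collapse = "")
  })
}

#' Generate a proteome with planted domain architectures
#'
#' Full-length genes carry one N-terminal then one C-terminal domain segment
#' separated by a linker of 10-50 residues; single-domain genes carry one
#' segment; decoys are i.i.d. background sequences. The truth records every
#' planted envelope with 1-based coordinates.
#'
#' @param ntd_profile,ctd_profile profiles the planted segments are sampled
#'   from.
#' @param n_full,n_ntd_only,n_ctd_only,n_decoy category counts (>= 0).
#' @param divergence per-site divergence of planted segments from the
#'   profile consensus.
#' @param decoy_length_range length range for decoy proteins.
#' @param seed RNG seed.
#' @return list with `seqs` (a [tps_seqs]) and `truth` (list:
#'   `planted_domains` data.frame with `gene_id`, `domain`, `start`, `end`,
#'   `divergence`; `census` with the three planted counts).
#' @export
generate_proteome <- function(ntd_profile, ctd_profile, n_full = 10,
                              n_ntd_only = 5, n_ctd_only = 5, n_decoy = 100,
                              divergence = 0.2,
                              decoy_length_range = c(200, 600), seed = 1) {
  stopifnot(n_full >= 0, n_ntd_only >= 0, n_ctd_only >= 0, n_decoy >= 0)
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    add_gene <- function(id, domains) {
      # domains: list of (profile, label); assembles flank-domain-linker-...
      parts <- random_protein(sample(20:80, 1))
      rows <- list()
      for (di in seq_along(domains)) {
        d <- domains[[di]]
        seg <- sample_domain_instance(d$profile, divergence,
                                      seed = sample.int(2^31 - 1, 1))
        start <- nchar(parts) + 1L
        parts <- paste0(parts, seg)
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = id, domain = d$label, start = start,
          end = nchar(parts), divergence = divergence,
          stringsAsFactors = FALSE)
        if (di < length(domains)) {
          parts <- paste0(parts, random_protein(sample(10:50, 1)))  # linker
        }
      }
      parts <- paste0(parts, random_protein(sample(20:80, 1)))
      seqs[[id]] <<- parts
      truth[[length(truth) + 1]] <<- do.call(rbind, rows)
    }
    ntd <- list(profile = ntd_profile, label = ntd_profile$label)
    ctd <- list(profile = ctd_profile, label = ctd_profile$label)
    for (i in seq_len(n_full)) {
      add_gene(sprintf("full_%04d", i), list(ntd, ctd))
    }
    for (i in seq_len(n_ntd_only)) {
      add_gene(sprintf("ntdonly_%04d", i), list(ntd))
    }
    for (i in seq_len(n_ctd_only)) {
      add_gene(sprintf("ctdonly_%04d", i), list(ctd))
    }
    for (i in seq_len(n_decoy)) {
      id <- sprintf("decoy_%04d", i)
      seqs[[id]] <- random_protein(sample(decoy_length_range[1]:decoy_length_range[2], 1))
    }
    planted <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), domain = character(),
                 start = integer(), end = integer(), divergence = numeric())
    list(seqs = tps_seqs(unlist(seqs)),
         truth = list(planted_domains = planted,
                      census = c(n_full = n_full, n_ntd_only = n_ntd_only,
                                 n_ctd_only = n_ctd_only)))
  })
}

#' Generate a genome layout with planted duplication structure
#'
#' Lays out filler genes, tandem arrays whose children satisfy all three
#' tandem rules, single-rule-violating control pairs, collinear duplicated
#' blocks of `block_pairs` anchor pairs on chromosome pairs, and LTR
#' elements with prescribed relations to designated genes. Gene spans are
#' ~2 kb with a few kb between neighbors.
#'
#' @param n_tandem_arrays number of planted tandem arrays.
#' @param array_size genes per array (parent + children), >= 2.
#' @param controls character vector of rule-violating control pairs to
#'   plant; any of `"rank"`, `"distance"`, `"identity"`, `"coverage"`.
#' @param n_blocks number of collinear duplicated blocks.
#' @param block_pairs anchor pairs per block (>= 5 for a positive block).
#' @param n_ltr number of LTR elements; relations cycle through
#'   `"contained"`, `"partial"`, `"flank_only"`, `"none"`.
#' @param genome_size assembly size in bp (drives the tandem bp window).
#' @param n_filler background genes per chromosome.
#' @param seed RNG seed.
#' @return list with `annotation` ([genome_annotation]), `elements`
#'   (data.frame), and `truth` (list: `tandem_pairs`, `control_pairs` with
#'   the violated rule, `blocks` as lists of anchor pairs,
#'   `element_overlaps` gene -> relation).
#' @export
generate_genome_layout <- function(n_tandem_arrays = 3, array_size = 2,
                                   controls = c("rank", "distance",
                                                "identity", "coverage"),
                                   n_blocks = 1, block_pairs = 5, n_ltr = 4,
                                   genome_size = 150e6, n_filler = 30,
                                   seed = 1) {
  stopifnot(array_size >= 2, n_tandem_arrays >= 0, n_blocks >= 0)
  window <- tandem_window(genome_size)
  with_seed(seed, {
    genes <- list()
    gid <- 0L
    cursor <- new.env()
    place <- function(chrom, gap, width = 2000, id = NULL) {
      pos <- get0(chrom, cursor, ifnotfound = 1) + gap
      gid <<- gid + 1L
      id <- id %||% sprintf("g%04d", gid)
      genes[[length(genes) + 1]] <<- data.frame(
        gene_id = id, chrom = chrom, start = pos, end = pos + width - 1,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      assign(chrom, pos + width, cursor)
      id
    }
    tandem_pairs <- list(); control_pairs <- list()
    # chromosome 1: filler genes, tandem arrays, control pairs interleaved
    for (i in seq_len(n_filler)) place("chr1", sample(3000:8000, 1))
    for (a in seq_len(n_tandem_arrays)) {
      parent <- place("chr1", sample(3000:8000, 1),
                      id = sprintf("tandemA%d_parent", a))
      for (c in seq_len(array_size - 1)) {
        child <- place("chr1", sample(2000:5000, 1),
                       id = sprintf("tandemA%d_child%d", a, c))
        tandem_pairs[[length(tandem_pairs) + 1]] <-
          data.frame(parent = parent, child = child, stringsAsFactors = FALSE)
      }
    }
    for (rule in controls) {
      p_id <- sprintf("ctrl_%s_parent", rule)
      c_id <- sprintf("ctrl_%s_child", rule)
      if (rule == "rank") {
        # 11 ranks apart but within the bp window
        parent <- place("chr1", sample(3000:5000, 1), id = p_id)
        for (f in seq_len(10)) place("chr1", 500, width = 1500)
        child <- place("chr1", 500, id = c_id)
      } else if (rule == "distance") {
        # adjacent in rank but separated by more than the window
        parent <- place("chr1", sample(3000:5000, 1), id = p_id)
        child <- place("chr1", window + 50000, id = c_id)
      } else {
        # proximity rules satisfied; sequence generation breaks the rule
        parent <- place("chr1", sample(3000:5000, 1), id = p_id)
        child <- place("chr1", sample(2000:5000, 1), id = c_id)
      }
      control_pairs[[length(control_pairs) + 1]] <-
        data.frame(parent = p_id, child = c_id, violated = rule,
                   stringsAsFactors = FALSE)
    }
    # collinear blocks on dedicated chromosome pairs
    blocks <- list()
    for (b in seq_len(n_blocks)) {
      ca <- sprintf("chr%d", 1 + 2 * b - 1 + 1)   # chr2, chr4, ...
      cb <- sprintf("chr%d", 1 + 2 * b + 1)       # chr3, chr5, ...
      pairs <- data.frame(geneA = character(), geneB = character())
      # noise partner placed before the block on the second chromosome so
      # the noise anchor crosses the block (never collinear with it)
      place(cb, sample(5000:15000, 1), id = sprintf("blk%d_noiseB", b))
      for (p in seq_len(block_pairs)) {
        ga <- place(ca, sample(5000:15000, 1), id = sprintf("blk%d_a%d", b, p))
        gb <- place(cb, sample(5000:15000, 1), id = sprintf("blk%d_b%d", b, p))
        pairs <- rbind(pairs, data.frame(geneA = ga, geneB = gb,
                                         stringsAsFactors = FALSE))
      }
      place(ca, sample(5000:15000, 1), id = sprintf("blk%d_noiseA", b))
      blocks[[b]] <- pairs
    }
    # LTR elements with prescribed relations on chr1 genes placed far apart
    relations <- rep(c("contained", "partial", "flank_only", "none"),
                     length.out = n_ltr)
    elements <- data.frame(chrom = character(), start = integer(),
                           end = integer(), feature_type = character())
    element_overlaps <- character(0)
    for (e in seq_len(n_ltr)) {
      g <- place("chr1", 150000, id = sprintf("ltr_%s_%d", relations[e], e))
      row <- genes[[length(genes)]]
      iv <- switch(relations[e],
        contained = c(row$start - 3000, row$end + 3000),
        partial = c(row$start - 3000, row$start + 500),
        flank_only = c(row$start - 40000, row$start - 35000),
        none = c(row$start - 70000, row$start - 62000))
      elements <- rbind(elements, data.frame(
        chrom = "chr1", start = iv[1], end = iv[2],
        feature_type = "LTR_retrotransposon", stringsAsFactors = FALSE))
      element_overlaps[g] <- relations[e]
    }
    gene_df <- do.call(rbind, genes)
    if (max(gene_df$end) > genome_size) {
      stop("layout infeasible: genes exceed genome_size")
    }
    annotation <- genome_annotation(gene_df, species = "synthetic",
                                    genome_size = genome_size)
    list(annotation = annotation, elements = elements,
         truth = list(tandem_pairs = do.call(rbind, tandem_pairs),
                      control_pairs = do.call(rbind, control_pairs),
                      blocks = blocks,
                      element_overlaps = element_overlaps))
  })
}

#' Generate proteins consistent with a layout truth
#'
#' Each tandem parent gets a random protein; children are copies substituted
#' at 5% of sites (identity ~0.95, coverage 1). The identity control child is
#' substituted at 60% of sites; the coverage control child keeps only the
#' first quarter of the parent followed by unrelated residues. All other
#' genes get unrelated random proteins.
#'
#' @param layout a [generate_genome_layout()] result.
#' @param protein_length length of the generated proteins.
#' @param seed RNG seed.
#' @return a [tps_seqs] with one protein per annotated gene.
#' @export
generate_family_proteins <- function(layout, protein_length = 300, seed = 1) {
  with_seed(seed, {
    ids <- layout$annotation$genes$gene_id
    seqs <- setNames(vapply(ids, function(i) random_protein(protein_length), ""),
                     ids)
    mutate <- function(s, rate) {
      chars <- strsplit(s, "")[[1]]
      hit <- runif(length(chars)) < rate
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA_ALPHABET20, a), 1)
      }, "")
      paste(chars, collapse = "")
    }
    tp <- layout$truth$tandem_pairs
    for (r in seq_len(NROW(tp))) {
      seqs[tp$child[r]] <- mutate(seqs[tp$parent[r]], 0.05)
    }
    cp <- layout$truth$control_pairs
    for (r in seq_len(NROW(cp))) {
      seqs[cp$child[r]] <- switch(cp$violated[r],
        identity = mutate(seqs[cp$parent[r]], 0.6),
        coverage = paste0(substr(seqs[cp$parent[r]], 1, protein_length %/% 4),
                          random_protein(protein_length -
                                         protein_length %/% 4)),
        mutate(seqs[cp$parent[r]], 0.05))   # rank/distance: sequence-similar
    }
    for (b in layout$truth$blocks) {
      for (r in seq_len(nrow(b))) {
        seqs[b$geneB[r]] <- mutate(seqs[b$geneA[r]], 0.05)
      }
    }
    tps_seqs(seqs)
  })
}

#' Generate a replicated expression matrix with planted structure
#'
#' Counts are drawn negative-binomially around per-tissue means. Planted
#' tissue-preferred genes have `fold` times the baseline mean in their
#' tissue; planted silent genes are all-zero; other genes are flat at the
#' baseline.
#'
#' @param gene_ids character vector of genes to emit.
#' @param tissues character vector of >= 2 tissue names.
#' @param replicates replicates per tissue (>= 2; the t-test is undefined
#'   below that).
#' @param preferred named character vector gene -> tissue for planted
#'   tissue-preferred genes.
#' @param silent character vector of planted all-zero genes.
#' @param fold preferred-tissue fold change (>= 1).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson noise.
#' @param baseline_mean baseline expected count.
#' @param seed RNG seed.
#' @return list with `table` (an [expression_table] in counts mode, gene
#'   lengths attached) and `truth` (`preferred`, `silent`).
#' @export
generate_expression <- function(gene_ids, tissues = c("root", "leaf", "stem"),
                                replicates = 3, preferred = character(0),
                                silent = character(0), fold = 8,
                                dispersion = 0.05, baseline_mean = 100,
                                seed = 1) {
  if (replicates < 2) stop("need >= 2 replicates per tissue (t-test undefined)")
  if (fold < 1) stop("fold must be >= 1")
  stopifnot(length(tissues) >= 2)
  with_seed(seed, {
    samples <- paste(rep(tissues, each = replicates),
                     rep(seq_len(replicates), length(tissues)), sep = "_")
    design <- data.frame(sample = samples,
                         tissue = rep(tissues, each = replicates),
                         replicate = rep(seq_len(replicates), length(tissues)),
                         stringsAsFactors = FALSE)
    draw <- function(mu) {
      if (mu == 0) return(0L)
      if (dispersion <= 0) return(rpois(1, mu))
      rnbinom(1, size = 1 / dispersion, mu = mu)
    }
    values <- matrix(0L, length(gene_ids), length(samples),
                     dimnames = list(gene_ids, samples))
    for (g in gene_ids) {
      for (s in seq_along(samples)) {
        mu <- if (g %in% silent) 0
              else if (g %in% names(preferred) &&
                       design$tissue[s] == preferred[[g]]) fold * baseline_mean
              else baseline_mean
        values[g, s] <- draw(mu)
      }
    }
    lengths <- setNames(sample(600:3000, length(gene_ids), replace = TRUE),
                        gene_ids)
    list(table = expression_table(values, design, mode = "counts",
                                  gene_lengths = lengths),
         truth = list(preferred = preferred, silent = silent))
  })
}

#' Simulate a coding-sequence pair with a known dN/dS
#'
#' A random stop-free ancestor of `n_codons` codons is evolved along two
#' lineages by repeated single-nucleotide proposals (uniform over the three
#' alternatives): synonymous changes are always accepted, nonsynonymous
#' changes with probability `omega`, and changes creating stop codons are
#' rejected. The realized process therefore has dN/dS = `omega` relative to
#' neutral opportunity.
#'
#' @param n_codons number of codons.
#' @param omega target dN/dS (in `[0, 1]` for purifying selection).
#' @param n_proposals proposal rounds per lineage (controls divergence).
#' @param seed RNG seed.
#' @return list with `cds_a`, `cds_b` (aligned, gap-free strings).
#' @export
simulate_codon_pair <- function(n_codons = 1000, omega = 0.5,
                                n_proposals = 600, seed = 1) {
  code <- genetic_code()
  bases <- c("T", "C", "A", "G")
  with_seed(seed, {
    sense <- names(code)[code != "*"]
    anc <- sample(sense, n_codons, replace = TRUE)
    evolve <- function(codons) {
      seq <- strsplit(paste(codons, collapse = ""), "")[[1]]
      n <- length(seq)
      for (r in seq_len(n_proposals)) {
        pos <- sample.int(n, 1)
        b <- sample(setdiff(bases, seq[pos]), 1)
        ci <- (pos - 1) %/% 3
        old_codon <- paste(seq[ci * 3 + 1:3], collapse = "")
        new_seq <- seq
        new_seq[pos] <- b
        new_codon <- paste(new_seq[ci * 3 + 1:3], collapse = "")
        if (code[[new_codon]] == "*") next
        if (code[[new_codon]] == code[[old_codon]] || runif(1) < omega) {
          seq <- new_seq
        }
      }
      paste(seq, collapse = "")
    }
    list(cds_a = evolve(anc), cds_b = evolve(anc))
  })
}

#' Write a full synthetic data set to a directory
#'
#' Convenience wrapper emitting `proteome.fasta`, `genes.gff3`,
#' `elements.bed`, `expr_counts.tsv`, `design.tsv`, `gene_lengths.tsv` and
#' `truth.json` as the file-level interface to the simulator.
#'
#' @param dir output directory (created if missing).
#' @param seed master RNG seed.
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ntd_seed <- simulate_seed_msa("NTD", length = 60, seed = seed)
  ctd_seed <- simulate_seed_msa("CTD", length = 70, seed = seed + 1)
  ntd <- build_profile(ntd_seed, label = "NTD")
  ctd <- build_profile(ctd_seed, label = "CTD")
  prot <- generate_proteome(ntd, ctd, seed = seed + 2)
  layout <- generate_genome_layout(seed = seed + 3)
  fam <- generate_family_proteins(layout, seed = seed + 4)
  expr <- generate_expression(layout$annotation$genes$gene_id,
                              preferred = setNames("root",
                                                   layout$annotation$genes$gene_id[1]),
                              seed = seed + 5)
  write_fasta(prot$seqs, file.path(dir, "proteome.fasta"))
  write_fasta(fam, file.path(dir, "family_proteins.fasta"))
  write_gff_genes(layout$annotation, file.path(dir, "genes.gff3"))
  write_elements_bed(layout$elements, file.path(dir, "elements.bed"))
  write_expression(expr$table, file.path(dir, "expr_counts.tsv"),
                   file.path(dir, "design.tsv"))
  write.table(data.frame(gene_id = names(expr$table$gene_lengths),
                         length_bp = unname(expr$table$gene_lengths)),
              file.path(dir, "gene_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(proteome = prot$truth,
                            layout = layout$truth,
                            expression = expr$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(list(proteome = prot, layout = layout, proteins = fam,
                 expression = expr))
}
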