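# Per-category indicator rates calibrated from the packaged reference
# table: column frequencies among the 65 printed risk genes, and the
# study-level category totals minus those columns for the remaining
# 567 background genes.
PLANTED_RATES <- c(missense = 16 / 65, cis_eqtl = 30 / 65, kegg = 15 / 65,
                   ppi = 46 / 65, ko_mice = 54 / 65)
BACKGROUND_RATES <- c(missense = 18 / 567, cis_eqtl = 38 / 567,
                      kegg = 1 / 567, ppi = 41 / 567, ko_mice = 5 / 567)

#' Configuration for the synthetic-input generator
#'
#' Defines the simulated study conditions: a universe of `n_genes`
#' genes covered by `n_snps` SNPs, of which `n_risk_genes` are planted
#' with elevated per-category annotation rates. The defaults mirror the
#' depression case study the packaged tables come from: 632 genes, 5885
#' SNPs, 65 planted risk genes, category rates calibrated from the
#' printed indicator columns.
#'
#' @param seed master seed; one derived stream per bundle component, so
#'   e.g. changing the drug settings does not perturb the SNP table.
#' @param n_genes universe size.
#' @param n_snps total SNP records (at least one per gene).
#' @param n_risk_genes number of planted risk genes.
#' @param planted_rates,background_rates named per-category Bernoulli
#'   rates (`missense`, `cis_eqtl`, `kegg`, `ppi`, `ko_mice`) for
#'   planted and background genes.
#' @param eqtl_tissue tissue label written for simulated cis-eQTLs.
#' @param n_filler_genes extra non-universe symbols available to gene
#'   sets (the annotation universe beyond the study genes).
#' @param planted_set_size target size of one planted (truly enriched)
#'   gene-set chunk; category-positive genes are split into near-equal
#'   chunks of about this size.
#' @param planted_filler_frac fraction of filler symbols mixed into each
#'   planted set.
#' @param n_noise_sets number of unenriched (noise) sets per collection.
#' @param noise_set_size length-2 range of noise-set sizes.
#' @param n_ppi_neighbors distinct new interactors planted on top of the
#'   risk genes at high confidence.
#' @param n_ppi_noise_edges additional lower-confidence edges.
#' @param druggable_frac fraction of (risk ∪ neighbor) genes given at
#'   least one drug.
#' @param drugs_per_gene length-2 range of drugs per druggable gene.
#' @param evidence_frac fraction of drugs given a development-evidence
#'   record.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 632L,
                             n_snps = 5885L,
                             n_risk_genes = 65L,
                             planted_rates = PLANTED_RATES,
                             background_rates = BACKGROUND_RATES,
                             eqtl_tissue = "Whole_Blood",
                             n_filler_genes = 2000L,
                             planted_set_size = 15L,
                             planted_filler_frac = 0.3,
                             n_noise_sets = 30L,
                             noise_set_size = c(10L, 40L),
                             n_ppi_neighbors = 50L,
                             n_ppi_noise_edges = 400L,
                             druggable_frac = 0.3,
                             drugs_per_gene = c(1L, 3L),
                             evidence_frac = 0.35) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_snps = as.integer(n_snps),
              n_risk_genes = as.integer(n_risk_genes),
              planted_rates = planted_rates,
              background_rates = background_rates,
              eqtl_tissue = eqtl_tissue,
              n_filler_genes = as.integer(n_filler_genes),
              planted_set_size = as.integer(planted_set_size),
              planted_filler_frac = planted_filler_frac,
              n_noise_sets = as.integer(n_noise_sets),
              noise_set_size = as.integer(noise_set_size),
              n_ppi_neighbors = as.integer(n_ppi_neighbors),
              n_ppi_noise_edges = as.integer(n_ppi_noise_edges),
              druggable_frac = druggable_frac,
              drugs_per_gene = as.integer(drugs_per_gene),
              evidence_frac = evidence_frac)
  nm <- names(PLANTED_RATES)
  if (!all(nm %in% names(cfg$planted_rates)) ||
      !all(nm %in% names(cfg$background_rates))) {
    stop_data("rates must be named for all five categories")
  }
  assert_prob(unlist(cfg[c("planted_rates", "background_rates")]), "rates")
  assert_prob(c(cfg$planted_filler_frac, cfg$druggable_frac,
                cfg$evidence_frac), "fractions")
  if (cfg$n_risk_genes > cfg$n_genes) {
    stop_data("planted risk genes cannot exceed the universe size")
  }
  if (cfg$n_snps < cfg$n_genes) {
    stop_data("need at least one SNP per gene (n_snps >= n_genes)")
  }
  structure(cfg, class = "generator_config")
}

# derived, reproducible stream per bundle component
component_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1021L + offset) %% 2147483629)
}

split_chunks <- function(x, target) {
  if (!length(x)) return(list())
  n_chunks <- max(1L, ceiling(length(x) / target))
  split(x, rep_len(seq_len(n_chunks), length(x)))
}

#' Generate a synthetic input bundle with planted signal
#'
#' Draws per-gene 0/1 indicators for the five annotation categories
#' (planted genes at elevated rates) and materializes every pipeline
#' input so that a faithful pipeline recovers the drawn signal: a SNP
#' table whose missense and whole-blood eQTL rows encode the two
#' variant-level indicators; three gene-set collections in which the
#' category-positive genes form strongly enriched planted sets beside
#' unenriched noise sets; a weighted interaction list with
#' high-confidence planted neighbors of the risk genes; and drug-target
#' and evidence tables for a druggable subset.
#'
#' @param config a [generator_config()].
#' @return a list of class `synthetic_bundle`: `snp_table`,
#'   `collections` (named list of [gene_set_collection()]s: `KEGG`,
#'   `GO_BP`, `MP`), `ppi`, `drug_targets`, `evidence`, `config`, and
#'   `ground_truth` (see details). Ground truth records `planted` (the
#'   designated risk-gene symbols), `profiles` (the drawn indicator
#'   matrix), `risk_genes` (genes whose drawn indicators sum to >= 2 —
#'   the true simulated labels), the planted set ids per collection,
#'   the planted network neighbors, the druggable genes, and the
#'   evidenced vs novel drugs.
#' @export
generate_bundle <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  nm <- names(PLANTED_RATES)

  symbols <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  gene_ids <- sprintf("ENSG%011d", seq_len(cfg$n_genes))
  filler <- if (cfg$n_filler_genes) {
    sprintf("FILL%04d", seq_len(cfg$n_filler_genes))
  } else character()

  # -- indicators ----------------------------------------------------
  set.seed(component_seed(cfg$seed, 1L))
  planted <- sort(sample(symbols, cfg$n_risk_genes))
  is_planted <- symbols %in% planted
  ind <- sapply(nm, function(cat) {
    rate <- ifelse(is_planted, cfg$planted_rates[[cat]],
                   cfg$background_rates[[cat]])
    rbinom(cfg$n_genes, 1L, rate)
  })
  truth_profiles <- data.frame(gene_id = gene_ids, gene_symbol = symbols,
                               ind, stringsAsFactors = FALSE)
  truth_profiles$total_score <- rowSums(truth_profiles[nm])
  true_risk <- symbols[truth_profiles$total_score >= 2]

  # -- SNP table -----------------------------------------------------
  set.seed(component_seed(cfg$seed, 2L))
  rows <- list()
  snp_no <- 0L
  next_snp <- function() {
    snp_no <<- snp_no + 1L
    sprintf("rs%07d", snp_no)
  }
  for (i in seq_len(cfg$n_genes)) {
    if (ind[i, "missense"] == 1L) {
      rows[[length(rows) + 1L]] <- c(next_snp(), gene_ids[i], symbols[i],
                                     "missense", "")
    }
    if (ind[i, "cis_eqtl"] == 1L) {
      rows[[length(rows) + 1L]] <- c(next_snp(), gene_ids[i], symbols[i],
                                     "intronic", cfg$eqtl_tissue)
    }
    rows[[length(rows) + 1L]] <- c(next_snp(), gene_ids[i], symbols[i],
                                   "intronic", "")
  }
  n_extra <- cfg$n_snps - length(rows)
  if (n_extra > 0) {
    gi <- sample.int(cfg$n_genes, n_extra, replace = TRUE)
    cons <- sample(c("intronic", "intergenic", "synonymous", "other"),
                   n_extra, replace = TRUE, prob = c(.6, .2, .15, .05))
    tis <- ifelse(runif(n_extra) < 0.05, "Brain_Cortex", "")
    for (j in seq_len(n_extra)) {
      rows[[length(rows) + 1L]] <- c(next_snp(), gene_ids[gi[j]],
                                     symbols[gi[j]], cons[j], tis[j])
    }
  }
  snp_table <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(snp_table) <- c("snp_id", "gene_id", "gene_symbol", "consequence",
                        "eqtl_tissue")
  snp_table <- snp_table[sample.int(nrow(snp_table)), ]
  rownames(snp_table) <- NULL

  # -- gene-set collections -----------------------------------------
  pool <- c(symbols, filler)
  make_collection <- function(cat, label, offset) {
    set.seed(component_seed(cfg$seed, offset))
    positives <- symbols[ind[, cat] == 1L]
    chunks <- split_chunks(sample(positives), cfg$planted_set_size)
    sets <- list()
    for (j in seq_along(chunks)) {
      pad <- max(0L, round(length(chunks[[j]]) * cfg$planted_filler_frac))
      members <- c(chunks[[j]],
                   if (pad && length(filler)) sample(filler, pad))
      sets[[sprintf("%s_PLANTED_%02d", label, j)]] <- members
    }
    for (j in seq_len(cfg$n_noise_sets)) {
      sz <- sample(cfg$noise_set_size[1]:cfg$noise_set_size[2], 1L)
      sets[[sprintf("%s_NOISE_%02d", label, j)]] <- sample(pool, sz)
    }
    # the generator knows its full annotation universe; declaring it as
    # the explicit background keeps the query a realistic minority of it
    gene_set_collection(sets, collection_id = label, background = pool)
  }
  collections <- list(KEGG  = make_collection("kegg", "KEGG", 3L),
                      GO_BP = make_collection("ppi", "GO_BP", 4L),
                      MP    = make_collection("ko_mice", "MP", 5L))

  # -- interaction network ------------------------------------------
  set.seed(component_seed(cfg$seed, 6L))
  neighbors <- if (cfg$n_ppi_neighbors) {
    sprintf("NBR%04d", seq_len(cfg$n_ppi_neighbors))
  } else character()
  anchor_pool <- if (length(true_risk)) true_risk else symbols
  anchors <- sample(anchor_pool, length(neighbors), replace = TRUE)
  planted_edges <- if (length(neighbors)) {
    data.frame(gene_a = anchors, gene_b = neighbors,
               confidence = runif(length(neighbors), 0.90, 0.999),
               stringsAsFactors = FALSE)
  } else NULL
  noise_a <- sample(pool, cfg$n_ppi_noise_edges, replace = TRUE)
  noise_b <- sample(pool, cfg$n_ppi_noise_edges, replace = TRUE)
  keep <- noise_a != noise_b
  noise_edges <- data.frame(gene_a = noise_a[keep], gene_b = noise_b[keep],
                            confidence = runif(sum(keep), 0.10, 0.85),
                            stringsAsFactors = FALSE)
  all_edges <- rbind(planted_edges, noise_edges)
  ppi <- ppi_edges(all_edges$gene_a, all_edges$gene_b, all_edges$confidence)

  # -- drugs and evidence -------------------------------------------
  set.seed(component_seed(cfg$seed, 7L))
  target_pool <- c(true_risk, neighbors)
  n_druggable <- round(length(target_pool) * cfg$druggable_frac)
  druggable <- sort(sample(target_pool, n_druggable))
  drug_rows <- list()
  drug_no <- 0L
  for (g in druggable) {
    n_d <- sample(cfg$drugs_per_gene[1]:cfg$drugs_per_gene[2], 1L)
    for (j in seq_len(n_d)) {
      drug_no <- drug_no + 1L
      drug_rows[[drug_no]] <- c(sprintf("drug%03d", drug_no), g,
                                sprintf("indication %d", drug_no))
    }
  }
  drug_targets <- if (drug_no) {
    dt <- as.data.frame(do.call(rbind, drug_rows), stringsAsFactors = FALSE)
    names(dt) <- c("drug_name", "gene_symbol", "original_indication")
    drug_target_table(dt$drug_name, dt$gene_symbol, dt$original_indication)
  } else {
    drug_target_table(character(), character(), character())
  }
  drugs <- unique(drug_targets$drug_name)
  evidenced <- sort(sample(drugs, round(length(drugs) * cfg$evidence_frac)))
  evidence <- if (length(evidenced)) {
    src <- sample(EVIDENCE_SOURCES, length(evidenced), replace = TRUE)
    id <- ifelse(src == "clinical",
                 sprintf("NCT%08d", sample.int(1e7, length(evidenced))),
                 sprintf("%d", sample.int(4e7, length(evidenced))))
    evidence_table(evidenced, src, id)
  } else {
    evidence_table(character(), character(), character())
  }

  structure(list(
    snp_table = snp_table,
    collections = collections,
    ppi = ppi,
    drug_targets = drug_targets,
    evidence = evidence,
    config = cfg,
    ground_truth = list(
      planted = planted,
      profiles = truth_profiles,
      risk_genes = true_risk,
      enriched_sets = lapply(collections, function(cl) {
        grep("_PLANTED_", names(cl$sets), value = TRUE)
      }),
      ppi_neighbors = neighbors,
      druggable_genes = druggable,
      evidenced_drugs = norm_drug(evidenced),
      novel_drugs = norm_drug(setdiff(drugs, evidenced))
    )
  ), class = "synthetic_bundle")
}

#' Write a synthetic bundle to a directory of standard files
#'
#' Emits `snps.tsv`, `kegg.gmt` / `go_bp.gmt` / `mp.gmt`,
#' `ppi_edges.tsv` (confidence on the 0-1000 integer scale),
#' `drug_targets.tsv`, `evidence.tsv` and `ground_truth.json`.
#'
#' @param bundle a `synthetic_bundle` from [generate_bundle()].
#' @param dir output directory, created if needed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tsv <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    p(f)
  }
  paths <- c(snps = tsv(bundle$snp_table, "snps.tsv"))
  gmt_files <- c(KEGG = "kegg.gmt", GO_BP = "go_bp.gmt", MP = "mp.gmt")
  for (id in names(gmt_files)) {
    write_gmt(bundle$collections[[id]]$sets, p(gmt_files[[id]]))
    paths[[id]] <- p(gmt_files[[id]])
  }
  bg <- unique(unlist(lapply(bundle$collections, `[[`, "background")))
  if (length(bg)) {
    writeLines(bg, p("background.txt"))
    paths[["background"]] <- p("background.txt")
  }
  edges_out <- data.frame(protein1 = bundle$ppi$gene_a,
                          protein2 = bundle$ppi$gene_b,
                          combined_score = round(bundle$ppi$confidence * 1000))
  paths[["ppi"]] <- tsv(edges_out, "ppi_edges.tsv")
  paths[["drug_targets"]] <- tsv(
    bundle$drug_targets[c("drug_name", "gene_symbol", "original_indication")],
    "drug_targets.tsv")
  paths[["evidence"]] <- tsv(
    bundle$evidence[c("drug_name", "source", "identifier")], "evidence.tsv")
  jsonlite::write_json(bundle$ground_truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths[["ground_truth"]] <- p("ground_truth.json")
  invisible(paths)
}

#' Construct an interaction list with a planted expansion outcome
#'
#' Builds an edge table in which the `n_new` strongest seed-incident
#' interactions each introduce one distinct new interactor, so that
#' expanding the seeds with `k = n_new` yields exactly
#' `length(seeds) + n_new` target genes. Lower-confidence distractor
#' edges (seed-seed, seed-neighbor and fully external pairs) are mixed
#' in to exercise the selection rule.
#'
#' @param seeds character vector of seed gene symbols.
#' @param n_new number of distinct planted interactors, default 50.
#' @param n_distractors number of distractor edges, default 150.
#' @param seed random seed for the distractor draw.
#' @return a `ppi_edges` data frame.
#' @export
make_planted_ppi <- function(seeds, n_new = 50, n_distractors = 150,
                             seed = 1L) {
  seeds <- sort(unique(norm_symbol(seeds)))
  set.seed(seed)
  new_genes <- sprintf("XNBR%04d", seq_len(n_new))
  planted <- data.frame(
    gene_a = sample(seeds, n_new, replace = TRUE),
    gene_b = new_genes,
    confidence = runif(n_new, 0.95, 0.999),
    stringsAsFactors = FALSE
  )
  ext <- sprintf("XEXT%04d", seq_len(max(4L, ceiling(n_distractors / 4))))
  d_a <- c(sample(seeds, n_distractors, replace = TRUE))
  d_b <- c(sample(c(seeds, new_genes, ext), n_distractors, replace = TRUE))
  # external-external pairs so that non-incident edges exist too
  e_a <- sample(ext, n_distractors %/% 3, replace = TRUE)
  e_b <- sample(ext, n_distractors %/% 3, replace = TRUE)
  da <- c(d_a, e_a); db <- c(d_b, e_b)
  keep <- da != db
  distract <- data.frame(gene_a = da[keep], gene_b = db[keep],
                         confidence = runif(sum(keep), 0.1, 0.9),
                         stringsAsFactors = FALSE)
  all <- rbind(planted, distract)
  out <- ppi_edges(all$gene_a, all$gene_b, all$confidence)
  # deduplication keeps the strongest score per pair, so the planted
  # edges are guaranteed to survive and outrank every distractor
  out
}
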