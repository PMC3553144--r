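#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file) with `out_dir`, `seed`,
#' a `stages` character vector and per-stage input paths/parameters. Every
#' referenced input file must exist; parameter ranges are checked before any
#' stage runs.
#'
#' @param config named list or path to a YAML file.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1, out_dir = "ankevol_out",
                   stages = c("similarity", "pest", "phylogeny",
                              "divergence", "kaks", "anm", "pca"),
                   bootstrap_replicates = 100, identity_min = 35,
                   anm_cutoff = 15, cutoff_type1 = 0.85, cutoff_type2 = 17,
                   min_occupancy = 0.9, metric = "similarity")
  for (k in names(defaults)) if (is.null(config[[k]]))
    config[[k]] <- defaults[[k]]
  known <- c("similarity", "pest", "phylogeny", "divergence", "kaks",
             "anm", "pca")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs <- list(similarity = c("fasta", "groups_tsv"), pest = "fasta",
                phylogeny = "msa", divergence = c("msa", "tree", "groups_tsv"),
                kaks = c("codon_msa", "kaks_query"), anm = "pdb",
                pca = c("pdb_list"))
  for (st in config$stages) for (k in needs[[st]]) {
    if (is.null(config[[k]]))
      stop("stage '", st, "' needs config field '", k, "'")
    if (k %in% c("fasta", "groups_tsv", "msa", "tree", "codon_msa", "pdb") &&
        !file.exists(config[[k]]))
      stop("stage '", st, "': input file not found: ", config[[k]])
  }
  if ("pca" %in% config$stages) {
    missing <- config$pdb_list[!file.exists(config$pdb_list)]
    if (length(missing))
      stop("stage 'pca': input file(s) not found: ",
           paste(missing, collapse = ", "))
  }
  stopifnot(config$bootstrap_replicates >= 1, config$anm_cutoff > 0,
            config$cutoff_type1 > 0, config$cutoff_type1 <= 1,
            config$min_occupancy > 0, config$min_occupancy <= 1)
  config
}

read_groups_tsv <- function(path) {
  g <- read.delim(path, header = FALSE, col.names = c("taxon", "group"),
                  stringsAsFactors = FALSE)
  setNames(g$group, g$taxon)
}

#' Run the multi-stage analysis pipeline
#'
#' Executes the enabled stages in dependency order: sequence similarity
#' table, PEST scan, NJ phylogeny with bootstrap, type I/II functional
#' divergence, site-wise Ka/Ks, ANM fluctuations, and ensemble PCA with
#' ANM overlap. Every output is a TSV under `out_dir`; a manifest (file,
#' stage, md5) and a provenance record (parameters, seed, input hashes) are
#' written alongside. Re-running the same configuration reproduces
#' identical tables.
#'
#' @param config list or YAML path, see [validate_config()].
#' @return (invisibly) the manifest data.frame.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), stage = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  emit <- function(df, name, stage) {
    path <- file.path(cfg$out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- rbind(manifest, data.frame(
      file = name, stage = stage, md5 = unname(tools::md5sum(path)),
      stringsAsFactors = FALSE))
    path
  }
  logmsg <- function(...) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                  " [ankevol] ", ...)
  run_stage <- function(st, fun) {
    logmsg("stage ", st, " started")
    tryCatch(fun(), error = function(e) {
      stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logmsg("stage ", st, " done")
  }

  if ("similarity" %in% cfg$stages) run_stage("similarity", function() {
    seqs <- read_fasta(cfg$fasta)
    gmap <- read_groups_tsv(cfg$groups_tsv)
    ids <- vapply(seqs, `[[`, "", "id")
    groups <- split(seqs, gmap[ids])
    gr <- group_range_matrix(groups, metric = cfg$metric)
    emit(as.data.frame(format_group_range(gr)), "similarity_table.tsv",
         "similarity")
  })

  if ("pest" %in% cfg$stages) run_stage("pest", function() {
    seqs <- read_fasta(cfg$fasta)
    rows <- do.call(rbind, lapply(seqs, function(s) {
      p <- find_pest(s)
      if (!nrow(p)) return(NULL)
      cbind(id = s$id, p)
    }))
    if (is.null(rows))
      rows <- data.frame(id = character(0), start = integer(0),
                         end = integer(0), length = integer(0),
                         score = numeric(0), valid = logical(0))
    emit(rows, "pest.tsv", "pest")
  })

  tree_path <- NULL
  if ("phylogeny" %in% cfg$stages) run_stage("phylogeny", function() {
    aln <- read_msa(cfg$msa)
    tr <- bootstrap_support(aln, replicates = cfg$bootstrap_replicates,
                            seed = cfg$seed)
    if (!is.null(cfg$outgroup)) tr <- root_with_outgroup(tr, cfg$outgroup)
    tree_path <<- file.path(cfg$out_dir, "nj_tree.nwk")
    write_newick(tr, tree_path)
    manifest <<- rbind(manifest, data.frame(
      file = "nj_tree.nwk", stage = "phylogeny",
      md5 = unname(tools::md5sum(tree_path)), stringsAsFactors = FALSE))
  })

  if ("divergence" %in% cfg$stages) run_stage("divergence", function() {
    aln <- read_msa(cfg$msa)
    tr <- read_newick(cfg$tree)
    gmap <- read_groups_tsv(cfg$groups_tsv)
    pairs <- taxonomic_grouping(aln, gmap, tr)
    rows <- lapply(names(pairs), function(nm) {
      pr <- pairs[[nm]]
      cnt <- fitch_counts(pr)
      t1 <- estimate_type1(cnt, pr, seed = cfg$seed)
      t2 <- estimate_type2(pr, cnt, cutoff = cfg$cutoff_type2)
      sites1 <- candidate_sites_type1(t1, cutoff = cfg$cutoff_type1)
      data.frame(comparison = nm, theta1 = t1$theta, se = t1$se,
                 lrt = t1$lrt, p_value = t1$p_value, theta2 = t2$theta2,
                 n_type1_sites = nrow(sites1),
                 n_type2_radical = length(t2$radical_sites),
                 stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "divergence.tsv", "divergence")
  })

  if ("kaks" %in% cfg$stages) run_stage("kaks", function() {
    aln <- read_msa(cfg$codon_msa, codon_mode = TRUE)
    res <- sitewise_kaks(aln, cfg$kaks_query)
    emit(res$per_codon, "kaks.tsv", "kaks")
    emit(data.frame(ka = res$overall$ka, ks = res$overall$ks,
                    omega = res$overall$omega), "kaks_overall.tsv", "kaks")
  })

  anm_profile <- NULL
  if ("anm" %in% cfg$stages) run_stage("anm", function() {
    st <- read_pdb_calpha(cfg$pdb)[[1]]
    modes <- anm_modes(build_hessian(st, r_c = cfg$anm_cutoff))
    prof <- mean_square_fluctuation(modes)
    tab <- data.frame(residue = seq_along(prof$msf), msf = prof$msf)
    if (!is.null(st$bfactors) && sd(st$bfactors) > 1e-12) {
      prof <- bfactor_compare(prof, st)
      tab$b_theoretical <- prof$b_theoretical
      tab$b_experimental <- st$bfactors
      tab$pearson_r <- prof$pearson_r
    }
    anm_profile <<- prof
    emit(tab, "anm_profile.tsv", "anm")
  })

  if ("pca" %in% cfg$stages) run_stage("pca", function() {
    structures <- unlist(lapply(cfg$pdb_list, read_pdb_calpha),
                         recursive = FALSE)
    ref <- if (!is.null(cfg$reference)) {
      hit <- which(vapply(structures, `[[`, "", "id") == cfg$reference)
      if (!length(hit)) stop("reference '", cfg$reference, "' not found")
      structures[[hit[1]]]
    } else structures[[1]]
    ens <- build_ensemble(structures, reference = ref,
                          min_occupancy = cfg$min_occupancy)
    ens <- iterative_superposition(ens)
    pca <- ensemble_pca(ens)
    emit(data.frame(conformer = ens$labels,
                    pc1 = pca$projections[, 1], pc2 = pca$projections[, 2],
                    rmsd_to_mean = ens$rmsd_to_mean),
         "pca_projections.tsv", "pca")
    emit(data.frame(pc = seq_along(pca$fractions),
                    fraction = pca$fractions), "pca_fractions.tsv", "pca")
    modes <- anm_modes(build_hessian(ens$reference$coords,
                                     r_c = cfg$anm_cutoff))
    ov <- mode_overlap(pca, modes)
    emit(cbind(data.frame(pc = rownames(ov$overlap)),
               as.data.frame(ov$overlap)), "overlap.tsv", "pca")
    emit(cbind(data.frame(pc = rownames(ov$projection_r)),
               as.data.frame(ov$projection_r)), "projection_r.tsv", "pca")
  })

  prov <- list(seed = cfg$seed, stages = cfg$stages,
               parameters = cfg[setdiff(names(cfg), c("stages", "out_dir"))],
               inputs = lapply(
                 cfg[intersect(names(cfg),
                               c("fasta", "groups_tsv", "msa", "tree",
                                 "codon_msa", "pdb"))],
                 function(p) unname(tools::md5sum(p))),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Fully synthetic end-to-end demonstration
#'
#' Generates every input with the package's synthetic-data module (protein
#' family with a planted rate shift, codon alignment, ankyrin-like chain,
#' conformer ensemble displaced along the chain's lowest ANM mode), then
#' runs the complete pipeline on them.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return (invisibly) the pipeline manifest.
#' @export
demo_pipeline <- function(out_dir = "ankevol_demo", seed = 1) {
  dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE,
             recursive = TRUE)
  inp <- function(f) file.path(out_dir, "inputs", f)

  tree <- divergence_study_tree()
  fam <- simulate_family(tree, L = 300, alpha = 0.5,
                         clusterB = grep("^b", tree$tip.label, value = TRUE),
                         theta = 0.4, seed = seed)
  write_fasta(fam$alignment$sequences, inp("family.fasta"))
  write_newick(tree, inp("family.nwk"))
  gmap <- ifelse(grepl("^a", tree$tip.label), "groupA", "groupB")
  write.table(data.frame(tree$tip.label, gmap), inp("groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)

  cod <- simulate_codons(tree, L_codons = 120,
                         omega_profile = rep(c(0.2, 1), each = 60),
                         seed = seed)
  write_fasta(cod$alignment$sequences, inp("codons.fasta"))

  ank <- make_ankyrin_calpha(4, seed = seed)
  ank$bfactors <- NULL
  modes <- anm_modes(build_hessian(ank))
  prof <- mean_square_fluctuation(modes)
  ank$bfactors <- round((8 * pi^2 / 3) * prof$msf /
                          max(prof$msf) * 60 + 10, 2)
  write_pdb_calpha(ank, inp("ankyrin.pdb"))
  me <- make_ensemble(ank, directions = matrix(modes$vectors[, 1], 1),
                      variances = 4, M = 12, seed = seed)
  pdb_list <- inp("ankyrin.pdb")
  for (m in seq_len(12)) {
    s <- ca_structure(sprintf("conf%02d", m), me$ensemble$coords[m, , ],
                      sequence = ank$sequence)
    f <- inp(sprintf("conf%02d.pdb", m))
    write_pdb_calpha(s, f)
    pdb_list <- c(pdb_list, f)
  }

  cfg <- list(seed = seed, out_dir = out_dir,
              fasta = inp("family.fasta"), groups_tsv = inp("groups.tsv"),
              msa = inp("family.fasta"), tree = inp("family.nwk"),
              codon_msa = inp("codons.fasta"),
              kaks_query = tree$tip.label[1],
              pdb = inp("ankyrin.pdb"), pdb_list = pdb_list,
              bootstrap_replicates = 50)
  run_pipeline(cfg)
}

#' Ensemble PCA summary for a directory of downloaded ARD structures
#'
#' Builds the matched C-alpha ensemble from every PDB file in `pdb_dir`
#' (each NMR model is one conformer), superposes it, runs PCA and returns
#' the headline quantities of the published ARD analysis: ensemble size,
#' the percent variance captured by PC1 + PC2, and the PC1 fraction. The
#' structure set itself (71 entries, Bcl3/1K1A as reference) is not
#' redistributable here and must be downloaded by the user.
#'
#' @param pdb_dir directory of PDB coordinate files.
#' @param reference_pattern regular expression (case-insensitive) selecting
#'   the reference structure by id (default the Bcl3 entry `"1k1a"`).
#' @param min_occupancy occupancy threshold for retained positions.
#' @return list with `M` (conformers), `pc12_pct`, `pc1_fraction`,
#'   `fractions`.
#' @export
literature_ensemble_summary <- function(pdb_dir, reference_pattern = "1k1a",
                                        min_occupancy = 0.9) {
  files <- list.files(pdb_dir, pattern = "\\.(pdb|ent)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop("no PDB files found in ", pdb_dir)
  structures <- unlist(lapply(files, read_pdb_calpha), recursive = FALSE)
  ids <- vapply(structures, `[[`, "", "id")
  hit <- grep(reference_pattern, ids, ignore.case = TRUE)
  if (!length(hit)) stop("reference matching '", reference_pattern,
                         "' not found among ", length(ids), " conformers")
  ens <- build_ensemble(structures, reference = structures[[hit[1]]],
                        min_occupancy = min_occupancy)
  ens <- iterative_superposition(ens)
  pca <- ensemble_pca(ens)
  list(M = dim(ens$coords)[1],
       pc12_pct = 100 * sum(pca$fractions[1:2]),
       pc1_fraction = pca$fractions[1],
       fractions = pca$fractions)
}

#' Balanced two-clade study trees for calibration simulations
#'
#' `study_tree()` builds a rooted tree of two balanced clades (`a...` and
#' `b...`) with `n_per_clade` tips each (a power of 2), tip branches `tip`,
#' intra-clade internal branches `internal` and a `separation` branch on
#' each side of the root.
#'
#' `divergence_study_tree()` is the default design for type I divergence
#' recovery: 8 sequences per cluster (two representatives from each of four
#' species classes, the grouping density used for subfamily comparisons)
#' at moderate within-cluster divergence, where parsimony substitution
#' counts track the true counts closely.
#'
#' `kaks_study_tree()` is the default design for Ka/Ks calibration: 4
#' sequences per clade at within-subfamily divergence (pairwise distances
#' ~0.3-0.6 substitutions/codon), the comfortable operating range of
#' counting estimators.
#'
#' @param n_per_clade tips per clade (power of 2, >= 4).
#' @param tip,internal,separation branch lengths (substitutions/site).
#' @return rooted [ape::phylo] tree with `2 * n_per_clade` tips.
#' @export
study_tree <- function(n_per_clade = 8, tip = 0.15, internal = 0.08,
                       separation = 0.2) {
  stopifnot(n_per_clade >= 4, bitwAnd(n_per_clade, n_per_clade - 1L) == 0L)
  clade <- function(prefix) {
    frag <- sprintf("%s%d:%g", prefix, seq_len(n_per_clade), tip)
    while (length(frag) > 1L) {
      frag <- vapply(seq_len(length(frag) / 2L), function(k)
        sprintf("(%s,%s):%g", frag[2 * k - 1L], frag[2 * k], internal), "")
    }
    sub(sprintf(":%g$", internal), "", frag)  # clade root gets separation
  }
  ape::read.tree(text = sprintf("(%s:%g,%s:%g);", clade("a"), separation,
                                clade("b"), separation))
}

#' @rdname study_tree
#' @export
divergence_study_tree <- function() study_tree(8, 0.15, 0.08, 0.2)

#' @rdname study_tree
#' @export
kaks_study_tree <- function() study_tree(4, 0.15, 0.08, 0.08)
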