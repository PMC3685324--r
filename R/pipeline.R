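## End-to-end orchestration: read -> filter -> diversity table -> pooled
## partitioned dN/dS -> NJ tree + bootstrap -> species-clustering
## permutation tests -> GC profiles + Welch tests -> outgroup pruning,
## ultrametricization and Brownian-motion clade models.

#' Run the full macroevolutionary analysis
#'
#' Executes every stage on a codon alignment with clade metadata and
#' writes report tables to `outdir`: `table1_diversity.tsv` (per-species
#' Na, S, pi, k, partitioned omega), `table2_dnds.tsv` (pooled partitioned
#' dN/dS per clade), `tree.nwk` (NJ tree with bootstrap support),
#' `permutation_tests.json`, `gc_profiles.tsv`, `gc_welch.json`,
#' `bm_models.tsv` (four Brownian-motion models x stem factors) and
#' `manifest.json` (seed, versions, per-stage runtimes). A stage failure
#' aborts with the stage name; earlier outputs are preserved.
#'
#' @param aln a [codon_alignment()], or path to an aligned FASTA
#' @param metadata path to the metadata TSV (when `aln` is a path)
#' @param outdir output directory (created if needed)
#' @param scheme a [partition_scheme()]
#' @param model,alpha distance model and gamma shape, see
#'   [pairwise_distance()]
#' @param n_boot bootstrap replicates for dN/dS SEs and tree support
#' @param n_rand random trees for the permutation test
#' @param stem_factors stem multipliers for the BM sensitivity analysis
#' @param seed master RNG seed, recorded in the manifest
#' @param min_nt_diff allele-filter threshold
#' @param R transition/transversion weight for dN/dS site counting
#' @param stages stages to run (default all); dependencies (`tree`, `gc`
#'   for `bmfit`) are added automatically
#' @param bm_tree optional rooted `phylo` (or newick path) used for the
#'   Brownian-motion stage in place of the estimated NJ tree; useful when
#'   the NJ tree does not recover the two clades as reciprocally
#'   monophyletic, which the clade models require
#' @return (invisibly) a list with all stage results
#' @export
run_full_analysis <- function(aln, metadata = NULL, outdir,
                              scheme = partition_scheme(),
                              model = "TN93G", alpha = 0.78,
                              n_boot = 100, n_rand = 1000,
                              stem_factors = c(1, 0.5), seed = 1,
                              min_nt_diff = 3, R = 0.5,
                              stages = c("diversity", "dnds", "tree",
                                         "permtest", "gc", "bmfit"),
                              bm_tree = NULL) {
  if ("bmfit" %in% stages) stages <- union(stages, c("tree", "gc"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(seed = seed)
  times <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  aln <- stage("read", {
    if (inherits(aln, "codon_alignment")) aln
    else read_codon_alignment(aln, metadata)
  })

  tab1 <- if ("diversity" %in% stages) stage("diversity", {
    t1 <- species_diversity_table(aln, scheme, min_nt_diff, R)
    write.table(t1, file.path(outdir, "table1_diversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    t1
  })

  tab2 <- if ("dnds" %in% stages) stage("dnds", {
    set.seed(seed)
    grp <- function(cl) aln$meta$id[aln$meta$clade == cl]
    t2 <- rbind(
      cbind(clade = "songbird",
            partitioned_dnds(aln, scheme, grp("songbird"), R, n_boot)),
      cbind(clade = "nonpasserine",
            partitioned_dnds(aln, scheme, grp("nonpasserine"), R, n_boot)))
    write.table(t2, file.path(outdir, "table2_dnds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    t2
  })

  tree <- if ("tree" %in% stages) stage("tree", {
    tr <- bootstrap_support(aln, model, alpha, n = n_boot, seed = seed)
    ape::write.tree(tr, file.path(outdir, "tree.nwk"))
    tr
  })

  perm <- if ("permtest" %in% stages) stage("permtest", {
    set.seed(seed + 1)
    one <- function(cl) {
      ids <- aln$meta$id[aln$meta$clade == cl]
      sub <- aln$mat[ids, , drop = FALSE]
      tr <- neighbor_joining(pairwise_distance(sub, model, alpha))
      states <- setNames(aln$meta$species[match(ids, aln$meta$id)], ids)
      r <- species_clustering_test(tr, states, n_rand = n_rand)
      r$null_steps <- NULL                     # keep the JSON small
      r
    }
    p <- list(songbird = one("songbird"), nonpasserine = one("nonpasserine"))
    jsonlite::write_json(p, file.path(outdir, "permutation_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    p
  })

  gc <- if ("gc" %in% stages) stage("gc", {
    g <- clade_gc_tests(aln)
    write.table(g$profiles, file.path(outdir, "gc_profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(gc3 = g$gc3, gc_all = g$gc_all),
                         file.path(outdir, "gc_welch.json"),
                         auto_unbox = TRUE, digits = NA)
    g
  })

  bm <- if ("bmfit" %in% stages) stage("bmfit", {
    og <- aln$meta$id[aln$meta$clade == "outgroup"]
    tr <- if (is.null(bm_tree)) tree
          else if (inherits(bm_tree, "phylo")) bm_tree
          else ape::read.tree(bm_tree)
    tr$node.label <- NULL
    og <- intersect(og, tr$tip.label)
    if (length(og)) {
      tr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
      tr <- ape::drop.tip(tr, og)
    }
    tr <- ultrametricize(tr)
    split <- clade_split(intersect(tr$tip.label,
                                   aln$meta$id[aln$meta$clade == "songbird"]),
                         intersect(tr$tip.label,
                                   aln$meta$id[aln$meta$clade == "nonpasserine"]))
    vals <- setNames(gc$profiles$gc3, gc$profiles$id)[tr$tip.label]
    tab <- clade_model_table(tr, vals, split, stem_factors)
    write.table(tab, file.path(outdir, "bm_models.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })

  manifest <- list(seed = seed, model = model, alpha = alpha,
                   n_boot = n_boot, n_rand = n_rand,
                   stem_factors = stem_factors,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("oscimhc")),
                   stage_seconds = times)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(aln = aln, table1 = tab1, table2 = tab2, tree = tree,
                 permutation = perm, gc = gc, bm = bm, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset) and `all` /
#' `diversity` / `dnds` / `tree` / `permtest` / `gc` / `bmfit` (run the
#' pipeline or a single stage). Flags: `--alignment`, `--metadata`,
#' `--partition` (file of exon codon numbers), `--frame-offset`,
#' `--model {tn93g,k2p}`, `--alpha`, `--boot`, `--nrand`,
#' `--stem-factors` (comma-separated), `--seed`, `--outdir`.
#'
#' @param args character vector (default: command-line arguments)
#' @return exit status, invisibly
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: <simulate|all|diversity|dnds|tree|permtest|gc|bmfit> ",
            "[--alignment F --metadata F --partition F --frame-offset N ",
            "--model tn93g --alpha A --boot N --nrand N ",
            "--stem-factors 1,0.5 --seed N --outdir D]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(alignment = NULL, metadata = NULL, partition = NULL,
              `frame-offset` = "4", model = "tn93g", alpha = "0.78",
              boot = "100", nrand = "1000", `stem-factors` = "1,0.5",
              seed = "1", outdir = "oscimhc_out")
  kv <- args[-1]
  i <- 1L
  while (i <= length(kv)) {
    key <- sub("^--", "", kv[i])
    if (!key %in% names(opt)) stop("unknown flag --", key)
    opt[[key]] <- kv[i + 1L]; i <- i + 2L
  }
  seed <- as.integer(opt$seed)
  scheme <- if (!is.null(opt$partition))
    read_partition_scheme(opt$partition, as.integer(opt$`frame-offset`))
  else partition_scheme(frame_offset = as.integer(opt$`frame-offset`))
  model <- if (tolower(opt$model) == "k2p") "K2P" else "TN93G"
  if (cmd == "simulate") {
    simulate_dataset(sim_config(seed = seed), scheme, outdir = opt$outdir)
    message("wrote synthetic dataset to ", opt$outdir)
    return(invisible(0L))
  }
  all_stages <- c("diversity", "dnds", "tree", "permtest", "gc", "bmfit")
  stages <- if (cmd == "all") all_stages
            else if (cmd %in% all_stages) cmd
            else stop("unknown subcommand '", cmd, "'")
  aln <- read_codon_alignment(opt$alignment, opt$metadata)
  stems <- as.numeric(strsplit(opt$`stem-factors`, ",")[[1]])
  run_full_analysis(aln, outdir = opt$outdir, scheme = scheme,
                    model = model, alpha = as.numeric(opt$alpha),
                    n_boot = as.integer(opt$boot),
                    n_rand = as.integer(opt$nrand),
                    stem_factors = stems, seed = seed, stages = stages)
  invisible(0L)
}
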