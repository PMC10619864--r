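# End-to-end orchestration with plain-file handoff: every stage reads and
# writes ordinary TSV/GFF3/FASTA/BED files so each is independently
# scriptable; a JSON manifest records config, checksums and timings.

validation_error <- function(...) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

dependency_error <- function(...) {
  stop(structure(class = c("dependency_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in the fixed order `simulate`, `tpm`,
#' `deg`, `dupmodes`, `kaks`, `islands`, `hubs`, `contam`, handing results
#' from stage to stage and writing each stage's outputs as plain files
#' under `outdir`. With `"simulate"` among the stages, inputs come from the
#' generator; otherwise `inputs` must provide file paths (`gff`, `counts`,
#' `design`, `homolog_pairs`, `cds`, `pairing`, `anchors`, `modules`,
#' `hits`, `query_lens`) as needed by the requested stages. A missing
#' upstream product raises a `dependency_error` naming the stage.
#'
#' @param config a [sim_config()] (used by the `simulate` stage and for the
#'   manifest snapshot).
#' @param outdir output directory.
#' @param stages character subset of the stage names above.
#' @param inputs named list of input file paths when not simulating.
#' @param deg_method internal DE method (see [call_degs()]).
#' @param island_patterns pattern sets to scan for islands.
#' @param trait_stage stage trait for hub selection.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` under `outdir`.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "tpm", "deg", "dupmodes",
                                    "kaks", "islands", "hubs", "contam"),
                         inputs = list(), deg_method = "welch",
                         island_patterns = c("H1UP", "H3UP", "H6UP", "H12UP"),
                         trait_stage = "H1") {
  order_all <- c("simulate", "tpm", "deg", "dupmodes", "kaks", "islands",
                 "hubs", "contam")
  bad <- setdiff(stages, order_all)
  if (length(bad)) validation_error("unknown stage: ", bad[1L])
  stages <- order_all[order_all %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  st <- new.env(parent = emptyenv())
  manifest <- list(
    package = tryCatch(as.character(utils::packageVersion("mossheat")),
                       error = function(e) "unknown"),
    config = unclass(config),
    stages = list()
  )
  outputs <- character(0)
  note <- function(stage, files, secs) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      seconds = round(secs, 3)
    )
    outputs <<- c(outputs, files)
  }
  need <- function(stage, what, ok) {
    if (!ok) dependency_error("stage '", stage, "' is missing upstream input: ", what)
  }
  input_path <- function(key) {
    p <- inputs[[key]]
    if (!is.null(p) && !file.exists(p)) {
      validation_error("input file for '", key, "' does not exist: ", p)
    }
    p
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- character(0)
    if (stage == "simulate") {
      st$bundle <- simulate_bundle(config)
      files <- write_bundle(st$bundle, file.path(outdir, "inputs"))
      st$ann <- st$bundle$ann
      st$counts <- st$bundle$counts
    } else if (stage == "tpm") {
      if (is.null(st$counts)) {
        cp <- input_path("counts"); dp <- input_path("design"); gp <- input_path("gff")
        need(stage, "counts/design/gff", !is.null(cp) && !is.null(dp) && !is.null(gp))
        st$ann <- read_gff3(gp)
        gl <- stats::setNames(st$ann$genes$end - st$ann$genes$start + 1L,
                              st$ann$genes$gene_id)
        st$counts <- read_counts(cp, dp, gl)
      }
      st$tpm <- counts_to_tpm(st$counts)
      f <- file.path(outdir, "tpm.tsv")
      write_tsv(data.frame(gene_id = rownames(st$tpm$values), st$tpm$values,
                           check.names = FALSE), f)
      files <- f
    } else if (stage == "deg") {
      need(stage, "tpm", !is.null(st$tpm))
      st$de <- call_degs(st$tpm, method = deg_method)
      st$patterns <- pattern_sets(st$de)
      f <- file.path(outdir, "deg.tsv")
      write_tsv(st$de, f)
      files <- f
    } else if (stage == "dupmodes") {
      if (is.null(st$ann)) {
        gp <- input_path("gff")
        need(stage, "gff", !is.null(gp))
        st$ann <- read_gff3(gp)
      }
      pairs <- if (!is.null(st$bundle)) st$bundle$homolog_pairs else {
        pp <- input_path("homolog_pairs")
        need(stage, "homolog_pairs", !is.null(pp))
        read_homolog_pairs(pp)
      }
      anchors <- if (!is.null(st$bundle)) st$bundle$interspecies_anchors else {
        ap <- input_path("anchors")
        if (is.null(ap)) character(0) else
          utils::read.delim(ap, stringsAsFactors = FALSE)$gene_id
      }
      st$blocks <- chain_collinear_blocks(pairs, st$ann)
      st$calls <- classify_duplicates(pairs, st$blocks, st$ann,
                                      interspecies_anchors = anchors)
      f1 <- file.path(outdir, "blocks.tsv")
      write_tsv(do.call(rbind, lapply(seq_along(st$blocks), function(i) {
        b <- st$blocks[[i]]
        data.frame(block = i, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
                   orientation = b$orientation, b$anchors,
                   stringsAsFactors = FALSE)
      })), f1)
      f2 <- file.path(outdir, "dup_calls.tsv")
      write_tsv(st$calls, f2)
      files <- c(f1, f2)
    } else if (stage == "kaks") {
      if (!is.null(st$bundle)) {
        cds <- st$bundle$cds
        pairing <- st$bundle$pairing
      } else {
        fp <- input_path("cds"); pp <- input_path("pairing")
        need(stage, "cds/pairing", !is.null(fp) && !is.null(pp))
        cds <- Biostrings::readDNAStringSet(fp)
        pairing <- utils::read.delim(pp, stringsAsFactors = FALSE)
      }
      st$kaks <- kaks_pairs(cds, pairing)
      f <- file.path(outdir, "kaks.tsv")
      write_tsv(st$kaks, f)
      files <- f
    } else if (stage == "islands") {
      need(stage, "deg", !is.null(st$de) && !is.null(st$tpm))
      need(stage, "annotation", !is.null(st$ann))
      expressed <- expressed_genes(st$tpm)
      f_all <- character(0)
      st$islands <- list()
      for (pat in island_patterns) {
        pat_genes <- intersect(st$patterns[[pat]], expressed)
        isl <- scan_islands(st$ann, pat_genes, expressed, de = st$de,
                            dup = st$calls,
                            contrast = paste0(sub("UP$", "", pat), "vsH0"))
        st$islands[[pat]] <- isl
        f <- file.path(outdir, paste0("islands_", pat, ".tsv"))
        write_tsv(isl[, setdiff(names(isl), "member_log2fc")], f)
        fb <- file.path(outdir, paste0("islands_", pat, ".bed"))
        islands_to_bed(isl, fb)
        f_all <- c(f_all, f, fb)
      }
      summ <- do.call(rbind, lapply(island_patterns, function(pat) {
        summarize_islands(st$islands[[pat]], pat,
                          length(st$patterns[[pat]]))
      }))
      fs <- file.path(outdir, "island_summary.tsv")
      write_tsv(summ, fs)
      files <- c(f_all, fs)
    } else if (stage == "hubs") {
      need(stage, "tpm", !is.null(st$tpm))
      modules <- if (!is.null(st$bundle)) st$bundle$modules else {
        mp <- input_path("modules")
        need(stage, "modules", !is.null(mp))
        utils::read.delim(mp, stringsAsFactors = FALSE)
      }
      st$hubs <- hub_select(st$tpm, modules, trait_stage)
      st$groups <- neighbor_groups(st$hubs, st$ann, st$calls)
      f1 <- file.path(outdir, "hubs.tsv")
      write_tsv(st$hubs, f1)
      f2 <- file.path(outdir, "neighbor_groups.tsv")
      write_tsv(st$groups, f2)
      files <- c(f1, f2)
    } else if (stage == "contam") {
      if (!is.null(st$bundle)) {
        hits <- read_blast_hits(st$bundle$hits, st$bundle$query_lens)
        all_q <- st$bundle$query_lens
      } else {
        hp <- input_path("hits"); qp <- input_path("query_lens")
        need(stage, "hits/query_lens", !is.null(hp) && !is.null(qp))
        all_q <- utils::read.delim(qp, stringsAsFactors = FALSE)
        hits <- read_blast_hits(hp, all_q)
      }
      st$verdicts <- screen_queries(hits, all_q)
      f <- file.path(outdir, "contam_verdicts.tsv")
      write_tsv(st$verdicts, f)
      files <- f
    }
    note(stage, files, proc.time()[["elapsed"]] - t0)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
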