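# Config-driven orchestration: compare -> enrich -> gsea -> funnel -> panel,
# with a line-oriented run log and machine-readable per-stage outputs. All
# outputs are timestamp-free so reruns with equal config and seeds are
# byte-identical.

#' Run the full analysis pipeline from a config
#'
#' The config (YAML file or equivalent list) registers DEG datasets and
#' requests any subset of the stages:
#'
#' * `datasets`: list of `{id, path, species, role}` DEG TSVs.
#' * `compare`: list of `{a, b, background}` dataset-pair comparisons.
#' * `enrich`: `{gmt, query: {dataset, direction}, background: [ids]}` ORA.
#' * `gsea`: `{gmt, ranked, n_perm, weight, seed}` ranked GSEA.
#' * `funnel`: per-species `{genome, tss, tss_format, blacklist,
#'   peaks: {FACTOR: [paths]}}` plus `pfm`, `orthologs`, `deg_2wk`,
#'   `deg_8wk`, optional `flank`, `p_cutoff`.
#' * `panel`: `{genes: [..] | "from_funnel", datasets: [ids]}`.
#'
#' Stages run in that order; a stage failure aborts the stages after it but
#' leaves completed outputs in place. Stochastic stages require an explicit
#' seed in the config.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return The run directory, invisibly; per-stage outputs live in
#'   subdirectories, the log in `run.log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: no output directory given")
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  alpha <- config$alpha %||% 0.05

  datasets <- list()
  for (d in config$datasets %||% list()) {
    cm <- if (!is.null(d$columns)) unlist(d$columns) else
      c(gene = "gene", log2fc = "log2fc", padj = "padj")
    tab <- withCallingHandlers(
      read_deg_table(d$path, d$id, d$species, column_map = cm),
      message = function(m) {
        note(sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    datasets[[d$id]] <- tab
    note("[INFO] dataset ", d$id, ": ", nrow(tab), " genes from ", d$path,
         " (md5 ", file_sha(d$path), ")")
  }

  status <- list()
  run_stage <- function(name, fun) {
    ok <- TRUE
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        note("[ERROR] stage ", name, " failed: ", conditionMessage(e))
        ok <<- FALSE
      }),
      message = function(m) {
        note(sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    status[[name]] <<- if (ok) "ok" else "failed"
    writeLines(log_lines, file.path(out_dir, "run.log"))
    if (!ok) stop("stage ", name, " failed; downstream stages skipped",
                  call. = FALSE)
    invisible(NULL)
  }

  funnel_result <- NULL

  if (!is.null(config$compare)) run_stage("compare", function() {
    for (cp in config$compare) {
      res <- compare_deg_tables(datasets[[cp$a]], datasets[[cp$b]],
                                background_n = cp$background, alpha = alpha)
      d <- file.path(out_dir, "compare", paste0(cp$a, "__", cp$b))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_json_file(unclass(res$overlap), file.path(d, "overlap.json"))
      write_json_file(res$concordance, file.path(d, "concordance.json"))
      write_tsv(data.frame(region = names(res$venn),
                           count = as.integer(res$venn)),
                file.path(d, "venn.tsv"))
      if (!is.null(res$correlation)) {
        sh <- res$correlation$shared_genes
        write_tsv(data.frame(
          gene = sh,
          log2fc_a = res$sig_a$log2fc[match(sh, res$sig_a$gene)],
          log2fc_b = res$sig_b$log2fc[match(sh, res$sig_b$gene)]),
          file.path(d, "shared_lfc.tsv"))
        write_json_file(res$correlation[c("rho", "p_value", "n_shared")],
                        file.path(d, "correlation.json"))
      }
      note("[INFO] compare ", cp$a, " vs ", cp$b, ": k=", res$overlap$k,
           " p=", signif(res$overlap$p_value, 4))
    }
  })

  if (!is.null(config$enrich)) run_stage("enrich", function() {
    e <- config$enrich
    catalog <- read_gmt(e$gmt)
    bg <- unique(unlist(lapply(e$background %||% names(datasets),
                               function(id) datasets[[id]]$gene)))
    q <- filter_significant(datasets[[e$query$dataset]], alpha,
                            direction = e$query$direction %||% "any")
    res <- ora(intersect(q$gene, bg), bg, catalog,
               min_size = e$min_size %||% 10, max_size = e$max_size %||% 500)
    d <- file.path(out_dir, "enrich")
    dir.create(d, showWarnings = FALSE)
    write_tsv(res, file.path(d, "ora.tsv"))
    if (isTRUE(e$simplify)) {
      sig <- res[res$padj < alpha, , drop = FALSE]
      write_tsv(simplify_terms(sig, catalog, e$simplify_cutoff %||% 0.7),
                file.path(d, "ora_simplified.tsv"))
    }
    note("[INFO] enrich: ", nrow(res), " terms tested, ",
         sum(res$padj < alpha), " significant")
  })

  if (!is.null(config$gsea)) run_stage("gsea", function() {
    g <- config$gsea
    if (is.null(g$seed)) stop("config error: gsea stage requires a seed")
    catalog <- read_gmt(g$gmt)
    ranked <- ranked_from_deg(datasets[[g$ranked]])
    res <- gsea_significance(ranked, catalog, n_perm = g$n_perm %||% 10000,
                             weight = g$weight %||% 1, seed = g$seed)
    d <- file.path(out_dir, "gsea")
    dir.create(d, showWarnings = FALSE)
    write_tsv(res, file.path(d, "gsea.tsv"))
    note("[INFO] gsea: ", nrow(res), " sets, seed ", g$seed)
  })

  if (!is.null(config$funnel)) run_stage("funnel", function() {
    f <- config$funnel
    load_sp <- function(sp) {
      peaks <- lapply(sp$peaks, function(paths) {
        do.call(rbind, lapply(paths, read_narrowpeak))
      })
      list(peaks = peaks,
           blacklist = if (!is.null(sp$blacklist)) read_bed(sp$blacklist),
           tss = read_tss(sp$tss, format = sp$tss_format %||% "bed6"),
           genome = read_genome(sp$genome))
    }
    res <- run_funnel(load_sp(f$human), load_sp(f$mouse),
                      pfms = read_jaspar_pfm(f$pfm),
                      orthologs = read_ortholog_map(f$orthologs),
                      deg_2wk = datasets[[f$deg_2wk]],
                      deg_8wk = datasets[[f$deg_8wk]],
                      flank = f$flank %||% 2000,
                      p_cutoff = f$p_cutoff %||% 5e-5, alpha = alpha)
    d <- file.path(out_dir, "funnel")
    dir.create(d, showWarnings = FALSE)
    write_tsv(res$panel, file.path(d, "panel.tsv"))
    write_json_file(as.list(res$stage_counts), file.path(d, "stage_counts.json"))
    write_tsv(data.frame(gene = names(res$elimination),
                         stage = unname(res$elimination)),
              file.path(d, "elimination.tsv"))
    funnel_result <<- res
    note("[INFO] funnel: ", paste(names(res$stage_counts),
                                  res$stage_counts, sep = "=",
                                  collapse = " "))
  })

  if (!is.null(config$panel)) run_stage("panel", function() {
    p <- config$panel
    genes <- if (identical(p$genes, "from_funnel")) {
      if (is.null(funnel_result)) stop("config error: no funnel stage ran")
      funnel_result$panel$gene
    } else unlist(p$genes)
    mats <- build_lfc_matrix(genes, datasets[unlist(p$datasets) %||% names(datasets)])
    d <- file.path(out_dir, "panel")
    dir.create(d, showWarnings = FALSE)
    export_matrix(mats, file.path(d, "matrix.tsv"))
    note("[INFO] panel: ", nrow(mats$lfc), " genes x ", ncol(mats$lfc),
         " datasets")
  })

  write_json_file(list(config = config, stages = status),
                  file.path(out_dir, "run_meta.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

validate_config <- function(config) {
  for (d in config$datasets %||% list()) {
    if (is.null(d$id) || is.null(d$path) || is.null(d$species)) {
      stop("config error: each dataset needs id, path, species")
    }
    if (!file.exists(d$path)) stop("config error: missing file ", d$path)
  }
  roles <- vapply(config$datasets %||% list(),
                  function(d) d$role %||% "", character(1))
  for (r in c("yt_2wk", "yt_8wk")) {
    if (sum(roles == r) > 1) stop("config error: role ", r, " must be unique")
  }
  invisible(TRUE)
}

#' Summarize a completed (or partial) pipeline run
#'
#' Aggregates a run directory's machine-readable outputs into a single JSON
#' document: overlap counts and percentages per comparison, concordance
#' fractions, correlation coefficients, enrichment counts, funnel stage
#' counts, and the panel gene list. Missing stages are marked, not errors.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return The summary list, invisibly; also written to `summary.json`.
#' @export
summarize_run <- function(run_dir) {
  meta_path <- file.path(run_dir, "run_meta.json")
  if (!file.exists(meta_path)) stop("missing run metadata in ", run_dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  summary <- list(stages = meta$stages)

  cmp_dir <- file.path(run_dir, "compare")
  if (dir.exists(cmp_dir)) {
    summary$comparisons <- lapply(list.dirs(cmp_dir, recursive = FALSE),
                                  function(d) {
      ov <- jsonlite::read_json(file.path(d, "overlap.json"),
                                simplifyVector = TRUE)
      cc <- jsonlite::read_json(file.path(d, "concordance.json"),
                                simplifyVector = TRUE)
      rr <- if (file.exists(file.path(d, "correlation.json"))) {
        jsonlite::read_json(file.path(d, "correlation.json"),
                            simplifyVector = TRUE)
      }
      list(pair = basename(d), k = ov$k,
           overlap_pct_of_b = 100 * ov$k / ov$n, p_value = ov$p_value,
           concordance = cc$fraction, rho = rr$rho)
    })
  } else summary$comparisons <- "missing"

  ora_path <- file.path(run_dir, "enrich", "ora.tsv")
  summary$enrichment <- if (file.exists(ora_path)) {
    tab <- read.delim(ora_path)
    list(n_terms = nrow(tab), n_significant = sum(tab$padj < 0.05))
  } else "missing"

  gsea_path <- file.path(run_dir, "gsea", "gsea.tsv")
  summary$gsea <- if (file.exists(gsea_path)) {
    tab <- read.delim(gsea_path)
    list(n_sets = nrow(tab), n_significant = sum(tab$padj < 0.05),
         top_nes = tab$nes[which.min(tab$p_value)])
  } else "missing"

  sc_path <- file.path(run_dir, "funnel", "stage_counts.json")
  if (file.exists(sc_path)) {
    summary$funnel_stage_counts <- jsonlite::read_json(sc_path,
                                                       simplifyVector = TRUE)
    panel <- read.delim(file.path(run_dir, "funnel", "panel.tsv"))
    summary$panel_genes <- panel$gene
  } else {
    summary$funnel_stage_counts <- "missing"
  }

  write_json_file(summary, file.path(run_dir, "summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

file_sha <- function(path) {
  unname(tools::md5sum(path))
}
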