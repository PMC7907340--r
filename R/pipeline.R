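#' Read a consumption-trial table
#'
#' Strict reader for the package's comma-separated trial schema. Required
#' columns: `predator_group`, `prey_type`, `density_offered`, `consumed`,
#' `dead_unconsumed`, `duration_days`, `replicate_id`, `excluded`. Unknown
#' columns are preserved. Rows violating the accounting constraint
#' `0 <= consumed + dead_unconsumed <= density_offered` (or with
#' non-numeric counts) are rejected with their line numbers.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame of trials.
#' @seealso [write_trials()], [generate_trials()]
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("predator_group", "prey_type", "density_offered", "consumed",
            "dead_unconsumed", "duration_days", "replicate_id", "excluded")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("trial table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("density_offered", "consumed", "dead_unconsumed",
                "duration_days")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  d$excluded <- as.logical(d$excluded)
  bad <- which(
    is.na(d$density_offered) | is.na(d$consumed) | is.na(d$dead_unconsumed) |
      is.na(d$duration_days) | is.na(d$excluded) |
      d$density_offered < 0 | d$consumed < 0 | d$dead_unconsumed < 0 |
      d$duration_days <= 0 |
      d$consumed + d$dead_unconsumed > d$density_offered)
  if (length(bad)) {
    stop("malformed trial row(s) at line ",
         paste(bad + 1L, collapse = ", "), " of ", path,
         " (counts must satisfy 0 <= consumed + dead_unconsumed <= ",
         "density_offered, duration > 0)")
  }
  d
}

#' Write a consumption-trial table
#'
#' @param trials data.frame in the trial schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a quadrat abundance table
#'
#' Required columns: `site`, `group`, `count`, `area_m2`, `source`
#' (`field` or `literature`). Malformed rows are rejected with line
#' numbers.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame of quadrat samples.
#' @export
read_quadrats <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "group", "count", "area_m2", "source")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("quadrat table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  d$count <- suppressWarnings(as.numeric(d$count))
  d$area_m2 <- suppressWarnings(as.numeric(d$area_m2))
  bad <- which(is.na(d$count) | d$count < 0 | is.na(d$area_m2) |
                 d$area_m2 <= 0 | !d$source %in% c("field", "literature"))
  if (length(bad)) {
    stop("malformed quadrat row(s) at line ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  d
}

#' Run the full comparative-impact pipeline
#'
#' Orchestrates simulate/load -> classify -> fit -> compare -> bootstrap ->
#' abundance -> RIP from a single configuration, writing machine-readable
#' CSV tables and a JSON log. Every stochastic stage draws its own seed
#' deterministically from the root `seed`, so a rerun with the same config
#' reproduces every table byte for byte.
#'
#' The configuration is a named list (or a path to a YAML/JSON file with
#' the same structure):
#' \preformatted{
#' seed: 42                      # mandatory
#' alpha: 0.05                   # optional, default 0.05
#' n_boot: 2000                  # bootstrap resamples (default 2000)
#' n_boot_fr: 30                 # small ensemble for max-feeding-rate SE
#' n_draws: 100000               # RIP Monte Carlo draws
#' feeding_rate: per_day         # or per_experiment
#' trials:                       # either `path:` or `simulate:`
#'   simulate:
#'     - {group: "large invader", prey: "embryo", a: 0.85, h: 0.258,
#'        T: 1, densities: [2,4,6,8,10,15,20,40,70], replicates: 5}
#' quadrats:
#'   simulate:
#'     - {group: "large invader", mean_density: 14.76, dispersion: 4,
#'        n_sites: 6}
#' compare:                      # pairs of group labels (base, comparator)
#'   - ["large invader", "intermediate invader"]
#' rip:                          # pairs of group labels (A, B)
#'   - ["large invader", "native"]
#' }
#' Exactly one of `path` / `simulate` must be present per data source.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir output directory for result tables (created if missing);
#'   `NULL` skips writing.
#' @return (invisibly) the result bundle: list with `fits`, `types`,
#'   `comparisons`, `boots`, `abundance`, `abundance_test`, `rip`,
#'   `tables` (the data.frames written to disk) and `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  seed <- cfg$seed
  if (is.null(seed)) stop("config must set a `seed` (stochastic stages)")
  check_count(seed, "seed")
  alpha <- cfg$alpha %||% 0.05
  n_boot <- cfg$n_boot %||% 2000
  n_boot_fr <- cfg$n_boot_fr %||% 30
  n_draws <- cfg$n_draws %||% 1e5
  convention <- match.arg(cfg$feeding_rate %||% "per_day",
                          c("per_day", "per_experiment"))
  log <- list(seed = seed, stages = list())

  ## ---- trials ----
  trials <- source_table(cfg$trials, "trials",
                         read = read_trials,
                         simulate = function(blocks) {
    do.call(rbind, lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      cc <- sim_config(a = b$a, h = b$h, T = b$T %||% 1,
                       densities = unlist(b$densities),
                       replicates = b$replicates %||% 5,
                       seed = derive_seed(seed, paste0("trials", i)),
                       predator_label = b$group %||% paste0("group", i),
                       prey_label = b$prey %||% "prey",
                       mortality_rate = b$mortality_rate %||% 0)
      generate_trials(cc)
    }))
  })
  excl <- sum(isTRUE_vec(trials$excluded))
  log$stages$trials <- list(n = nrow(trials), excluded = excl)

  groups <- unique(trials$predator_group)
  per_group <- split(trials, trials$predator_group)[groups]

  ## ---- classify + fit + bootstrap ----
  types <- lapply(per_group, classify_fr_type, alpha = alpha)
  fits <- lapply(per_group, fit_rogers)
  boots <- lapply(names(fits), function(g) {
    bootstrap_fit(fits[[g]], n_boot = n_boot,
                  seed = derive_seed(seed, paste0("boot_", g)))
  })
  names(boots) <- names(fits)
  boots_fr <- lapply(names(fits), function(g) {
    bootstrap_fit(fits[[g]], n_boot = n_boot_fr,
                  seed = derive_seed(seed, paste0("bootfr_", g)))
  })
  names(boots_fr) <- names(fits)
  log$stages$bootstrap <- lapply(boots, function(b) {
    list(n_boot = b$n_boot, n_failed = b$n_failed)
  })

  fits_tab <- do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(group = g, parameter = c("a", "h"),
               estimate = unname(coef(f)), se = unname(f$se),
               z = unname(f$z), p = unname(f$p),
               fr_type = types[[g]]$classified_type,
               max_feeding_rate = f$max_feeding_rate,
               max_feeding_rate_per_day = f$max_feeding_rate_per_day,
               stringsAsFactors = FALSE)
  }))

  ## ---- comparisons ----
  comparisons <- list()
  comp_tab <- NULL
  for (pair in cfg$compare %||% list()) {
    pair <- unlist(pair)
    if (!all(pair %in% groups)) {
      stop("compare stage: unknown group(s) ",
           paste(setdiff(pair, groups), collapse = ", "))
    }
    cmp <- compare_fits(per_group[[pair[1L]]], per_group[[pair[2L]]])
    key <- paste(pair, collapse = " vs ")
    comparisons[[key]] <- cmp
    comp_tab <- rbind(comp_tab, data.frame(
      base = pair[1L], comparator = pair[2L],
      parameter = c("Da", "Dh"),
      estimate = c(cmp$Da, cmp$Dh), se = c(cmp$se_Da, cmp$se_Dh),
      z = unname(cmp$z), p = unname(cmp$p), stringsAsFactors = FALSE))
  }

  ## ---- abundance ----
  abund <- abund_test <- NULL
  if (!is.null(cfg$quadrats)) {
    quad <- source_table(cfg$quadrats, "quadrats",
                         read = read_quadrats,
                         simulate = function(blocks) {
      do.call(rbind, lapply(seq_along(blocks), function(i) {
        b <- blocks[[i]]
        generate_quadrat_survey(
          mean_density_per_m2 = b$mean_density, dispersion = b$dispersion,
          n_sites = b$n_sites, area_m2 = b$area_m2 %||% 0.25,
          seed = derive_seed(seed, paste0("quadrats", i)),
          group = b$group %||% paste0("group", i))
      }))
    })
    abund <- summarize_abundance(quad)
    if (length(unique(quad$group)) >= 2L) {
      abund_test <- compare_abundance(quad, alpha = alpha)
    }
    log$stages$abundance <- list(n_samples = nrow(quad))
  }

  ## ---- RIP ----
  effects <- list()
  if (!is.null(abund)) {
    for (g in intersect(names(boots_fr), abund$group)) {
      fr <- if (convention == "per_day") {
        boots_fr[[g]]$max_feeding_rate_per_day
      } else {
        boots_fr[[g]]$max_feeding_rate
      }
      row <- abund[abund$group == g, ]
      effects[[g]] <- effect_summary(g, fr$mean, fr$se,
                                     row$mean_density, row$se_density)
    }
  }
  rips <- list()
  rip_tab <- NULL
  for (pair in cfg$rip %||% list()) {
    pair <- unlist(pair)
    if (!all(pair %in% names(effects))) {
      stop("rip stage: no effect summary for group(s) ",
           paste(setdiff(pair, names(effects)), collapse = ", "),
           " (needs both a fit and abundance)")
    }
    r <- rip_score(effects[[pair[1L]]], effects[[pair[2L]]],
                   n_draws = n_draws,
                   seed = derive_seed(seed, paste("rip", pair[1L], pair[2L])))
    key <- paste(pair, collapse = " vs ")
    rips[[key]] <- r
    rip_tab <- rbind(rip_tab, data.frame(
      A = pair[1L], B = pair[2L], rip_mean = r$rip_mean,
      ci60_low = r$CI60[1L], ci60_high = r$CI60[2L],
      ci80_low = r$CI80[1L], ci80_high = r$CI80[2L],
      prob_exceeds_one = r$prob_exceeds_one, n_draws = r$n_draws,
      stringsAsFactors = FALSE))
  }

  ## ---- curve + biplot data ----
  curve_tab <- do.call(rbind, lapply(names(boots), function(g) {
    b <- boots[[g]]$band
    b$fit <- predict(fits[[g]], b$density_offered)
    cbind(group = g, b, stringsAsFactors = FALSE)
  }))
  biplot <- if (length(effects) >= 2L) rip_biplot_data(unname(effects))

  tables <- list(fits = fits_tab, comparisons = comp_tab, rip = rip_tab,
                 fr_curves = curve_tab,
                 abundance = if (!is.null(abund)) as.data.frame(abund),
                 biplot_points = if (!is.null(biplot)) biplot$points,
                 biplot_isoclines = if (!is.null(biplot)) biplot$isoclines)
  tables <- Filter(Negate(is.null), tables)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(fits = fits, types = types, comparisons = comparisons,
                 boots = boots, boots_fr = boots_fr, abundance = abund,
                 abundance_test = abund_test, effects = effects, rip = rips,
                 biplot = biplot, tables = tables, log = log))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = FALSE),
      stop("config must be a .yaml/.yml or .json file, got .", ext))
  }
  if (!is.list(config)) stop("`config` must be a named list or a file path")
  config
}

# a data-source block must name exactly one of `path` / `simulate`
source_table <- function(block, what, read, simulate) {
  if (is.null(block)) stop("config is missing the `", what, "` block")
  has_path <- !is.null(block$path)
  has_sim <- !is.null(block$simulate)
  if (has_path == has_sim) {
    stop("`", what, "` must specify exactly one of `path` or `simulate`")
  }
  if (has_path) read(block$path) else simulate(block$simulate)
}
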