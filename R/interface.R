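# Configuration files, result serialization, and run dispatch: the
# programmatic surface behind the command-line tool.

#' Load a run configuration from a JSON or YAML file
#'
#' The file describes the medium (one `layer` entry per layer with keys
#' `mu_a`, `mu_s` (or `musp`), `g` or `phase`, `n`, `thickness`, optional
#' `fluorescence` block), external indices, the `beam`, and a `solver`
#' block (`type` pn/de/mc, `N`, `precision`, `domain`, grids, `seed`,
#' `photons`). Unknown keys are rejected.
#'
#' @param path file path (`.json`, `.yml`, `.yaml`).
#' @return a validated `lux_run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    fix_yaml_keys(yaml::read_yaml(path))
  else jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(raw$solver))
    names(raw$solver)[names(raw$solver) == "n"] <- "N"
  parse_run_config(raw, src = path)
}

# YAML 1.1 parses the bare keys y/n as booleans; map them back to the
# refractive-index key they stand for in medium tables
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    nm[nm == "TRUE"] <- "y"
    names(x) <- nm
  }
  lapply(x, fix_yaml_keys)
}

known_keys <- list(
  top = c("layer", "layers", "n_external_top", "n_external_bottom", "beam",
          "solver", "name"),
  layer = c("mu_a", "mu_s", "musp", "g", "phase", "n", "thickness",
            "fluorescence"),
  fluor = c("mu_a", "mu_s", "musp", "g", "quantum_yield"),
  beam = c("profile", "rho_w", "radius"),
  solver = c("type", "N", "precision", "domain", "r", "t", "q", "seed",
             "photons", "r_edges", "t_edges", "contour", "M"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
}

parse_phase <- function(lay, where) {
  if (!is.null(lay$phase)) {
    p <- lay$phase
    switch(tolower(p$family),
           hg = phase_hg(p$g),
           rmcc = phase_rmcc(p$g, p$alpha),
           rayleigh = phase_rayleigh(),
           table = read_phase_table(p$file),
           stop("unknown phase family in ", where))
  } else if (!is.null(lay$g)) phase_hg(lay$g)
  else stop("layer in ", where, " needs 'g' or 'phase'")
}

parse_layer_optics <- function(lay, where) {
  ph <- parse_phase(lay, where)
  th <- lay$thickness
  if (is.character(th)) {
    if (!tolower(th) %in% c("inf", "infinity")) stop("bad thickness in ", where)
    th <- Inf
  }
  g <- phase_g(ph)
  mu_s <- if (!is.null(lay$mu_s)) lay$mu_s
          else if (!is.null(lay$musp)) lay$musp / (1 - g)
          else stop("layer in ", where, " needs mu_s or musp")
  layer_optics(lay$mu_a, mu_s, ph, lay$n %||% 1.4, th)
}

parse_run_config <- function(raw, src = "<config>") {
  check_keys(raw, known_keys$top, src)
  lays <- raw$layer %||% raw$layers
  if (is.null(lays)) stop("config has no layers")
  if (!is.null(names(lays))) lays <- list(lays)
  fluor <- any(vapply(lays, function(l) !is.null(l$fluorescence), TRUE))
  media <- lapply(lays, function(l) {
    check_keys(l, known_keys$layer, "layer")
    base <- parse_layer_optics(l, "layer")
    if (is.null(l$fluorescence)) return(list(x = base, m = NULL, yield = 0))
    fl <- l$fluorescence
    check_keys(fl, known_keys$fluor, "layer.fluorescence")
    fl$n <- base$n; fl$thickness <- base$thickness
    if (is.null(fl$g) && is.null(fl$phase)) fl$g <- layer_g(base)
    em <- parse_layer_optics(fl, "layer.fluorescence")
    list(x = base, m = em, yield = fl$quantum_yield %||% 0)
  })
  net <- raw$n_external_top %||% 1.0
  neb <- raw$n_external_bottom %||% 1.0
  if (fluor) {
    fls <- lapply(media, function(m) {
      em <- m$m %||% m$x
      fluorescent_layer(m$x, em, m$yield)
    })
    problem <- fluorescence_problem(fls, net, neb)
    medium <- problem$medium_x
  } else {
    problem <- NULL
    medium <- layered_medium(lapply(media, `[[`, "x"), net, neb)
  }
  braw <- raw$beam
  if (is.null(braw)) {
    message("no beam table; defaulting to a Gaussian beam with rho_w = 0.5 mm")
    bm <- beam("gaussian", 0.5)
  } else {
    check_keys(braw, known_keys$beam, "beam")
    bm <- beam(braw$profile %||% "gaussian", rho_w = braw$rho_w %||% 0.5,
               radius = braw$radius %||% 1)
  }
  sv <- raw$solver %||% list()
  check_keys(sv, known_keys$solver, "solver")
  cfg <- structure(list(
    medium = medium, problem = problem, beam = bm,
    solver = tolower(sv$type %||% "pn"),
    N = sv$N %||% 9,
    precision = sv$precision %||% "double",
    domain = tolower(sv$domain %||% "spatial"),
    r = sv$r %||% seq(0.25, 10, by = 0.25),
    t = sv$t %||% exp(seq(log(20), log(3000), length.out = 60)),
    q = sv$q %||% seq(0, 5, by = 0.1),
    contour = sv$contour %||% "two_part",
    M = sv$M %||% 64,
    seed = sv$seed %||% 1,
    photons = sv$photons %||% 1e6,
    r_edges = sv$r_edges %||% seq(0, 10, by = 0.5),
    t_edges = sv$t_edges %||% numeric(0),
    name = raw$name %||% "run",
    raw = raw), class = "lux_run_config")
  cfg
}

#' Serialize a run configuration back to a list/JSON form
#' @param config a `lux_run_config`.
#' @export
serialize_config <- function(config) config$raw

config_hash <- function(config) {
  s <- jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE)
  # small stable polynomial hash; avoids extra dependencies
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 1000000007
  sprintf("%09d", h)
}

#' Execute a run configuration
#'
#' Dispatches to the requested solver and domain and (optionally) writes a
#' commented CSV plus a JSON metadata sidecar.
#'
#' @param config a `lux_run_config` from [load_config()].
#' @param out optional output path prefix (writes `<out>.csv`,
#'   `<out>.json`).
#' @return the result object (data frame or `lux_mc_result`), invisibly
#'   when writing files.
#' @export
run <- function(config, out = NULL) {
  stopifnot(inherits(config, "lux_run_config"))
  pcfg <- pn_config(N = config$N, precision = config$precision)
  res <- switch(paste(config$solver, config$domain, sep = "."),
    pn.spatial = if (!is.null(config$problem))
        fluorescence_spatial_curve(config$problem, config$beam, pcfg, config$r)
      else steady_state_curve(config$medium, config$beam, pcfg, config$r),
    pn.time = time_resolved_curve(config$medium, config$beam, pcfg,
                                  r = config$r[1], t_grid = config$t,
                                  type = config$contour, M = config$M),
    pn.sfd = reflectance_sfd_curve(config$medium, config$beam, pcfg, config$q),
    de.spatial = if (!is.null(config$problem))
        de_fluorescence_spatial_curve(config$problem, config$beam, config$r)
      else de_spatial_curve(config$medium, config$beam, config$r),
    de.time = de_time_curve(config$medium, config$beam, config$r[1], config$t),
    mc.spatial = ,
    mc.time = {
      mcc <- mc_config(config$photons, config$seed,
                       r_edges = config$r_edges, t_edges = config$t_edges)
      if (!is.null(config$problem))
        run_fluorescence(config$problem, config$beam, mcc)
      else run_elastic(config$medium, config$beam, mcc)
    },
    stop("unsupported solver/domain combination: ",
         config$solver, "/", config$domain))
  if (!is.null(out)) {
    write_result(res, paste0(out, ".csv"), config)
    jsonlite::write_json(
      list(config = serialize_config(config), hash = config_hash(config),
           solver = config$solver, domain = config$domain,
           generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      paste0(out, ".json"), auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Write a result table as commented CSV
#'
#' @param res a spatial/time result data frame or `lux_mc_result`.
#' @param path output file.
#' @param config optional `lux_run_config` recorded in the header.
#' @export
write_result <- function(res, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layerlux %s", as.character(utils::packageVersion("layerlux"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  if (inherits(res, "lux_mc_result")) {
    writeLines(sprintf("# mc: n_photons=%g seed=%g specular=%g reflected=%g transmitted=%g absorbed=%s guard=%g",
                       res$n_photons, res$seed, res$counts$specular,
                       res$counts$reflected, res$counts$transmitted,
                       paste(res$counts$absorbed, collapse = "/"),
                       res$counts$guard), con)
    df <- res$Rr
  } else {
    for (a in c("N", "solver", "contour"))
      if (!is.null(attr(res, a)))
        writeLines(sprintf("# %s: %s", a, attr(res, a)), con)
    df <- as.data.frame(res)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare two result tables
#'
#' Computes the relative-error table `(a - b)/b` on the shared grid; when
#' `se` is supplied (an MC comparand), adds error-over-SE and a chi-square
#' summary.
#'
#' @param a,b numeric vectors or result data frames with matching grids
#'   (column `R`).
#' @param se optional standard errors of `b`.
#' @param tol pass/fail threshold on `max(abs(rel))` (ignored when `NULL`).
#' @return list with `rel`, summary statistics and logical `pass`.
#' @export
compare_results <- function(a, b, se = NULL, tol = NULL) {
  va <- if (is.data.frame(a)) a$R else a
  vb <- if (is.data.frame(b)) b$R else b
  if (length(va) != length(vb)) stop("grid mismatch")
  rel <- (va - vb) / vb
  out <- list(rel = rel, max_abs_rel = max(abs(rel)),
              median_abs_rel = stats::median(abs(rel)))
  if (!is.null(se)) {
    z <- (va - vb) / se
    out$z <- z
    out$chisq <- sum(z^2)
    out$dof <- length(z)
  }
  if (!is.null(tol)) out$pass <- out$max_abs_rel <= tol
  out
}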