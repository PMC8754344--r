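# ---------------------------------------------------------------------------
# Four-layer XML model specification: stimulation, network architecture,
# morphology and biophysics, each in its own file, resolved into an
# in-memory model.  Mathematical expressions (e.g. synapse density) are
# parsed from a restricted declarative dialect.
# ---------------------------------------------------------------------------

.spec_err <- function(layer, element, msg)
  stop(sprintf("model spec [%s/%s]: %s", layer, element, msg), call. = FALSE)

.attr_num <- function(node, name, layer, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) {
    if (is.null(default))
      .spec_err(layer, xml2::xml_name(node),
                paste("missing required attribute", name))
    return(default)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out))
    .spec_err(layer, xml2::xml_name(node),
              paste("attribute", name, "is not numeric"))
  out
}

.attr_chr <- function(node, name, layer, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) {
    if (is.null(default))
      .spec_err(layer, xml2::xml_name(node),
                paste("missing required attribute", name))
    return(default)
  }
  v
}

#' Parse a restricted mathematical expression
#'
#' Accepts arithmetic on the variable `x` with the functions `max`, `min`,
#' `tanh`, `exp`, `log`, `sqrt` and `abs` only; anything else is rejected.
#'
#' @param text the expression, e.g.
#'   `"max(1 - (0.254 * 0.5 * (1 + tanh(x - 102)) + 0.6144), 0)"`.
#' @return a vectorized function of `x`.
#' @export
parse_expression <- function(text) {
  allowed <- c("max", "min", "tanh", "exp", "log", "sqrt", "abs", "pmax",
               "pmin", "+", "-", "*", "/", "^", "(")
  expr <- tryCatch(parse(text = text)[[1]],
                   error = function(e) stop("unparsable expression: ", text))
  check <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% allowed)
        stop("disallowed function in expression: ", fn)
      for (a in as.list(e)[-1]) check(a)
    } else if (is.name(e)) {
      if (!identical(as.character(e), "x"))
        stop("only the variable 'x' is allowed, found: ", as.character(e))
    } else if (!is.numeric(e)) {
      stop("disallowed token in expression")
    }
  }
  check(expr)
  # vector-safe variants of max/min
  env <- list2env(list(max = function(...) do.call(pmax, list(...)),
                       min = function(...) do.call(pmin, list(...))),
                  parent = baseenv())
  function(x) eval(expr, envir = list(x = x), enclos = env)
}

.read_stimulation <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  kind <- .attr_chr(root, "kind", "stimulation")
  noise_node <- xml2::xml_find_first(doc, ".//noise")
  noise <- if (!inherits(noise_node, "xml_missing"))
    flicker_noise_spec(
      n_spots = .attr_num(noise_node, "n_spots", "stimulation", 30),
      spot_radius = .attr_num(noise_node, "spot_radius", "stimulation", 25),
      refresh_rate = .attr_num(noise_node, "refresh_rate", "stimulation", 15),
      rng_seed = .attr_num(noise_node, "rng_seed", "stimulation", 1))
  fs <- c(.attr_num(root, "field_width", "stimulation"),
          .attr_num(root, "field_height", "stimulation"))
  ctr <- c(.attr_num(root, "center_x", "stimulation"),
           .attr_num(root, "center_y", "stimulation"))
  if (kind %in% c("expanding_rings", "collapsing_rings")) {
    ring_stimulus(kind, field_size = fs, center = ctr,
                  field_origin = c(.attr_num(root, "origin_x",
                                             "stimulation", 0),
                                   .attr_num(root, "origin_y",
                                             "stimulation", 0)),
                  temporal_frequency = .attr_num(root, "temporal_frequency",
                                                 "stimulation", 2),
                  spatial_period = .attr_num(root, "spatial_period",
                                             "stimulation", 450),
                  delay = .attr_num(root, "delay", "stimulation", 0),
                  duration = .attr_num(root, "duration", "stimulation"),
                  noise = noise)
  } else if (kind == "alternating_bar") {
    bar_stimulus(bar_length = .attr_num(root, "bar_length", "stimulation"),
                 bar_width = .attr_num(root, "bar_width", "stimulation"),
                 velocity = .attr_num(root, "velocity", "stimulation"),
                 x_perimeter = .attr_num(root, "x_perimeter", "stimulation"),
                 center = ctr,
                 first_direction = .attr_num(root, "first_direction",
                                             "stimulation", 1),
                 duration = .attr_num(root, "duration", "stimulation"),
                 field_size = fs, noise = noise)
  } else {
    .spec_err("stimulation", "stimulation", paste("unknown kind", kind))
  }
}

.read_morphologies <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//morphology")
  if (length(nodes) == 0L)
    .spec_err("morphology", "morphologies", "no morphology elements")
  out <- list()
  meta <- list()
  for (nd in nodes) {
    id <- .attr_chr(nd, "id", "morphology")
    src <- .attr_chr(nd, "source", "morphology")
    kind <- .attr_chr(nd, "cell_kind", "morphology", "SAC")
    if (src == "star") {
      args <- list(n_primary = .attr_num(nd, "n_primary", "morphology", 6),
                   total_extent = .attr_num(nd, "total_extent",
                                            "morphology", 210),
                   branch_orders = .attr_num(nd, "branch_orders",
                                             "morphology", 2),
                   cell_kind = kind)
      m <- do.call(generate_star_sac, args)
      meta[[id]] <- c(list(source = "star"), args)
    } else if (src == "swc") {
      p <- .attr_chr(nd, "path", "morphology")
      if (!file.exists(p))
        .spec_err("morphology", id, paste("SWC file not found:", p))
      m <- read_swc(p, cell_kind = kind)
      corr <- .attr_num(nd, "radius_correction", "morphology", 1)
      if (corr != 1) m <- apply_radius_correction(m, corr)
      meta[[id]] <- list(source = "swc", path = p, radius_correction = corr,
                         cell_kind = kind)
    } else {
      .spec_err("morphology", id, paste("unknown source", src))
    }
    out[[id]] <- m
  }
  list(morphologies = out, meta = meta)
}

.read_architecture <- function(path) {
  doc <- xml2::read_xml(path)
  pops <- xml2::xml_find_all(doc, ".//population")
  if (length(pops) == 0L)
    .spec_err("architecture", "architecture", "no population elements")
  populations <- lapply(pops, function(p) {
    grids <- lapply(xml2::xml_find_all(p, ".//grid"), function(g)
      list(nx = .attr_num(g, "nx", "architecture"),
           ny = .attr_num(g, "ny", "architecture"),
           spacing = .attr_num(g, "spacing", "architecture"),
           x0 = .attr_num(g, "x0", "architecture", 0),
           y0 = .attr_num(g, "y0", "architecture", 0)))
    list(id = .attr_chr(p, "id", "architecture"),
         morphology = .attr_chr(p, "morphology", "architecture"),
         grids = grids)
  })
  intra <- lapply(xml2::xml_find_all(doc, ".//intra_synapses"), function(s)
    list(population = .attr_chr(s, "population", "architecture"),
         conductance = .attr_num(s, "conductance", "architecture"),
         distal_fraction = .attr_num(s, "distal_fraction", "architecture",
                                     1 / 3),
         threshold = .attr_num(s, "threshold", "architecture", 5),
         e_rev = .attr_num(s, "e_rev", "architecture", -75)))
  projections <- lapply(xml2::xml_find_all(doc, ".//projection"), function(s)
    list(from = .attr_chr(s, "from", "architecture"),
         to = .attr_chr(s, "to", "architecture"),
         rule = .attr_chr(s, "rule", "architecture", "asymmetric"),
         conductance = .attr_num(s, "conductance", "architecture"),
         pd = c(.attr_num(s, "pd_x", "architecture", 1),
                .attr_num(s, "pd_y", "architecture", 0)),
         threshold = .attr_num(s, "threshold", "architecture", 5),
         e_rev = .attr_num(s, "e_rev", "architecture", -60)))
  list(populations = populations, intra = intra, projections = projections)
}

.read_biophysics <- function(path) {
  doc <- xml2::read_xml(path)
  cells <- xml2::xml_find_all(doc, ".//cell")
  out <- list()
  for (cd in cells) {
    pop <- .attr_chr(cd, "population", "biophysics")
    pn <- xml2::xml_find_first(cd, ".//passive")
    passive <- if (!inherits(pn, "xml_missing"))
      passive_props(
        axial_resistivity = .attr_num(pn, "axial_resistivity",
                                      "biophysics", 75),
        specific_capacitance = .attr_num(pn, "specific_capacitance",
                                         "biophysics", 1),
        leak_conductance = .attr_num(pn, "leak_conductance", "biophysics",
                                     6e-5),
        resting_potential = .attr_num(pn, "resting_potential", "biophysics",
                                      -60))
      else passive_props()
    bn <- xml2::xml_find_first(cd, ".//bc_synapses")
    genome <- NULL
    if (!inherits(bn, "xml_missing")) {
      args <- lapply(.ga_param_names, function(nm)
        .attr_num(bn, nm, "biophysics",
                  unlist(genome_params())[[nm]]))
      names(args) <- .ga_param_names
      genome <- do.call(genome_params, args)
    }
    dn <- xml2::xml_find_first(cd, ".//density")
    density_fn <- if (!inherits(dn, "xml_missing"))
      parse_expression(.attr_chr(dn, "expr", "biophysics"))
    out[[pop]] <- list(passive = passive, genome = genome,
                       density = density_fn)
  }
  out
}

#' Load and resolve a four-file model specification
#'
#' Reads the stimulation, architecture, morphology and biophysics layers,
#' validates cross-references (every population must name an existing
#' morphology; every biophysics cell an existing population), and resolves
#' them into an in-memory model.
#'
#' @param stimulation,architecture,morphology,biophysics file paths.
#' @return a `model_spec`: stimulus spec, morphologies, population layouts
#'   (data frames of soma positions), connectivity rules and per-population
#'   biophysics.
#' @export
load_model_spec <- function(stimulation, architecture, morphology,
                            biophysics) {
  stim <- .read_stimulation(stimulation)
  mor <- .read_morphologies(morphology)
  arch <- .read_architecture(architecture)
  bio <- .read_biophysics(biophysics)
  for (p in arch$populations)
    if (!p$morphology %in% names(mor$morphologies))
      .spec_err("architecture", p$id,
                paste("references missing morphology id", p$morphology))
  pop_ids <- vapply(arch$populations, `[[`, character(1), "id")
  for (nm in names(bio))
    if (!nm %in% pop_ids)
      .spec_err("biophysics", nm, "references missing population id")
  for (s in arch$intra)
    if (!s$population %in% pop_ids)
      .spec_err("architecture", "intra_synapses",
                paste("references missing population id", s$population))
  for (s in arch$projections)
    for (ref in c(s$from, s$to))
      if (!ref %in% pop_ids)
        .spec_err("architecture", "projection",
                  paste("references missing population id", ref))
  layouts <- lapply(arch$populations, function(p) {
    rows <- do.call(rbind, lapply(p$grids, function(g) {
      gg <- expand.grid(ix = seq_len(g$nx) - 1L, iy = seq_len(g$ny) - 1L)
      data.frame(x = g$x0 + gg$ix * g$spacing, y = g$y0 + gg$iy * g$spacing)
    }))
    rows$cell <- seq_len(nrow(rows))
    rows
  })
  names(layouts) <- pop_ids
  structure(list(stimulus = stim, morphologies = mor$morphologies,
                 morphology_meta = mor$meta, populations = arch$populations,
                 layouts = layouts, intra = arch$intra,
                 projections = arch$projections, biophysics = bio),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s stimulus, %d population(s), %d morpholog%s>\n",
              x$stimulus$kind, length(x$populations),
              length(x$morphologies),
              if (length(x$morphologies) == 1) "y" else "ies"))
  invisible(x)
}

#' Serialize a resolved model back to the four-file XML dialect
#'
#' @param model a [load_model_spec()] result.
#' @param dir output directory; writes stimulation.xml, architecture.xml,
#'   morphology.xml, biophysics.xml.
#' @return named vector of the four file paths, invisibly.
#' @export
write_model_spec <- function(model, dir) {
  stopifnot(inherits(model, "model_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(v) sprintf("%.10g", v)
  # stimulation
  st <- model$stimulus
  stim_doc <- xml2::xml_new_root("stimulation", kind = st$kind,
                                 duration = num(st$duration),
                                 field_width = num(st$field_size[1]),
                                 field_height = num(st$field_size[2]),
                                 center_x = num(st$center[1]),
                                 center_y = num(st$center[2]))
  if (st$kind == "alternating_bar") {
    xml2::xml_set_attrs(stim_doc, c(xml2::xml_attrs(stim_doc),
      bar_length = num(st$bar_length), bar_width = num(st$bar_width),
      velocity = num(st$velocity), x_perimeter = num(st$x_perimeter),
      first_direction = num(st$first_direction)))
  } else {
    xml2::xml_set_attrs(stim_doc, c(xml2::xml_attrs(stim_doc),
      origin_x = num(st$field_origin[1]), origin_y = num(st$field_origin[2]),
      temporal_frequency = num(st$temporal_frequency),
      spatial_period = num(st$spatial_period), delay = num(st$delay)))
  }
  if (!is.null(st$noise))
    xml2::xml_add_child(stim_doc, "noise",
                        n_spots = num(st$noise$n_spots),
                        spot_radius = num(st$noise$spot_radius),
                        refresh_rate = num(st$noise$refresh_rate),
                        rng_seed = num(st$noise$rng_seed))
  # morphology
  mor_doc <- xml2::xml_new_root("morphologies")
  for (id in names(model$morphology_meta)) {
    mm <- model$morphology_meta[[id]]
    if (mm$source == "star") {
      xml2::xml_add_child(mor_doc, "morphology", id = id, source = "star",
                          n_primary = num(mm$n_primary),
                          total_extent = num(mm$total_extent),
                          branch_orders = num(mm$branch_orders),
                          cell_kind = mm$cell_kind)
    } else {
      xml2::xml_add_child(mor_doc, "morphology", id = id, source = "swc",
                          path = mm$path,
                          radius_correction = num(mm$radius_correction),
                          cell_kind = mm$cell_kind)
    }
  }
  # architecture
  arch_doc <- xml2::xml_new_root("architecture")
  for (p in model$populations) {
    pn <- xml2::xml_add_child(arch_doc, "population", id = p$id,
                              morphology = p$morphology)
    for (g in p$grids)
      xml2::xml_add_child(pn, "grid", nx = num(g$nx), ny = num(g$ny),
                          spacing = num(g$spacing), x0 = num(g$x0),
                          y0 = num(g$y0))
  }
  for (s in model$intra)
    xml2::xml_add_child(arch_doc, "intra_synapses", population = s$population,
                        conductance = num(s$conductance),
                        distal_fraction = num(s$distal_fraction),
                        threshold = num(s$threshold), e_rev = num(s$e_rev))
  for (s in model$projections)
    xml2::xml_add_child(arch_doc, "projection", from = s$from, to = s$to,
                        rule = s$rule, conductance = num(s$conductance),
                        pd_x = num(s$pd[1]), pd_y = num(s$pd[2]),
                        threshold = num(s$threshold), e_rev = num(s$e_rev))
  # biophysics
  bio_doc <- xml2::xml_new_root("biophysics")
  for (pop in names(model$biophysics)) {
    b <- model$biophysics[[pop]]
    cn <- xml2::xml_add_child(bio_doc, "cell", population = pop)
    pp <- b$passive
    xml2::xml_add_child(cn, "passive",
                        axial_resistivity = num(pp$axial_resistivity),
                        specific_capacitance = num(pp$specific_capacitance),
                        leak_conductance = num(pp$leak_conductance),
                        resting_potential = num(pp$resting_potential))
    if (!is.null(b$genome)) {
      gv <- genome_to_vec(b$genome)
      do.call(xml2::xml_add_child,
              c(list(cn, "bc_synapses"),
                as.list(setNames(vapply(gv, num, character(1)), names(gv)))))
    }
  }
  paths <- c(stimulation = file.path(dir, "stimulation.xml"),
             architecture = file.path(dir, "architecture.xml"),
             morphology = file.path(dir, "morphology.xml"),
             biophysics = file.path(dir, "biophysics.xml"))
  xml2::write_xml(stim_doc, paths["stimulation"])
  xml2::write_xml(arch_doc, paths["architecture"])
  xml2::write_xml(mor_doc, paths["morphology"])
  xml2::write_xml(bio_doc, paths["biophysics"])
  invisible(paths)
}
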