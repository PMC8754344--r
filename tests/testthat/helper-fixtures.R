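# Shared fixtures, built in code at test time.

# a soma plus one straight cable section of constant radius
cable_morphology <- function(length_um = 400, radius_um = 1,
                             soma_radius = 1, step = 10) {
  pts <- cbind(seq(0, length_um, by = step), 0, 0)
  sections <- list(
    list(id = 1L, parent = NA_integer_,
         points = rbind(c(0, 0, -soma_radius), c(0, 0, soma_radius)),
         radii = c(soma_radius, soma_radius)),
    list(id = 2L, parent = 1L, points = pts,
         radii = rep(radius_um, nrow(pts))))
  structure(list(sections = sections, soma_center = c(0, 0, 0),
                 cell_kind = "SAC"), class = "morphology")
}

# minimal star used by smoke tests
small_star <- function() generate_star_sac(n_primary = 3L, total_extent = 60,
                                           branch_orders = 1L)

write_swc_fixture <- function(lines, path = tempfile(fileext = ".swc")) {
  writeLines(lines, path)
  path
}

# 3-sample unbranched cell with a single-sample soma
swc_simple <- function() write_swc_fixture(c(
  "# simple three-point cell",
  "1 1 0 0 0 2 -1",
  "2 3 10 0 0 1 1",
  "3 3 10 5 0 0.5 2"))

swc_branched <- function() write_swc_fixture(c(
  "1 1 0 0 0 2 -1",
  "2 3 10 0 0 1 1",
  "3 3 0 10 0 1 1"))

# hand-written golden four-layer model spec in a temp directory
write_spec_fixture <- function(dir = tempfile("spec")) {
  dir.create(dir)
  writeLines(paste0(
    '<stimulation kind="expanding_rings" duration="1500" field_width="315"',
    ' field_height="315" center_x="135" center_y="125" origin_x="0"',
    ' origin_y="0" temporal_frequency="2" spatial_period="450" delay="0"/>'),
    file.path(dir, "stimulation.xml"))
  writeLines(c('<morphologies>',
               paste0('  <morphology id="sac" source="star" n_primary="6"',
                      ' total_extent="210" branch_orders="2"',
                      ' cell_kind="SAC"/>'),
               '</morphologies>'), file.path(dir, "morphology.xml"))
  writeLines(c('<architecture>',
               '  <population id="sacs" morphology="sac">',
               '    <grid nx="3" ny="3" spacing="125" x0="0" y0="0"/>',
               '    <grid nx="2" ny="2" spacing="125" x0="62" y0="67"/>',
               '  </population>',
               paste0('  <intra_synapses population="sacs" conductance="0.1"',
                      ' distal_fraction="0.333333" threshold="5"',
                      ' e_rev="-75"/>'),
               '</architecture>'), file.path(dir, "architecture.xml"))
  writeLines(c('<biophysics>',
               '  <cell population="sacs">',
               paste0('    <passive axial_resistivity="75"',
                      ' specific_capacitance="1" leak_conductance="6e-05"',
                      ' resting_potential="-60"/>'),
               paste0('    <bc_synapses refilling_rate="3.7"',
                      ' release_probability="0.08"',
                      ' k_transition_start_point="0"',
                      ' k_transition_end_point="135"',
                      ' synaptic_conductance="0.0025"',
                      ' anatomical_transition_point="102"',
                      ' scaling_factor="0.254" offset="0.6144"/>'),
               '  </cell>',
               '</biophysics>'), file.path(dir, "biophysics.xml"))
  dir
}

load_spec_fixture <- function(dir = write_spec_fixture()) {
  load_model_spec(stimulation = file.path(dir, "stimulation.xml"),
                  architecture = file.path(dir, "architecture.xml"),
                  morphology = file.path(dir, "morphology.xml"),
                  biophysics = file.path(dir, "biophysics.xml"))
}
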