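# Transcription of the published xFP-chromophore parameter set: the bond,
# angle, dihedral, improper, and nonbonded terms needed beyond ff14SB/ff19SB
# for the seven chromophores.  gaff values are from gaff version 1.81.
# Values are stored exactly as printed; the frcmod emitter is the test
# surface for this transcription.

.xfp_bond_table <- function() {
  b <- rbind(
    # direct matches for gaff parameters
    c("cc", "cd", 500.9, 1.3729, "gaff cc-cd"),
    c("cd", "cd", 419.8, 1.4278, "gaff cd-cd"),
    c("cc", "nc", 441.1, 1.3694, "gaff cc-nc"),
    c("cd", "nc", 525.4, 1.3172, "gaff cd-nc"),
    c("cd", "nd", 441.1, 1.3694, "gaff cd-nd"),
    c("cc", "c", 371.0, 1.4676, "gaff c-cc"),
    c("c", "nd", 416.9, 1.3867, "gaff c-nd"),
    c("cc", "ha", 349.1, 1.0837, "gaff cc-ha"),
    c("cd", "ha", 349.1, 1.0837, "gaff cd-ha"),
    c("cf", "cf", 382.8, 1.4574, "gaff cf-cf"),
    c("cf", "ne", 564.4, 1.2964, "gaff cf-ne"),
    c("cf", "nf", 406.9, 1.3942, "gaff cf-nf"),
    c("c", "nf", 411.2, 1.3909, "gaff c-nf"),
    c("c", "o", 637.7, 1.2183, "gaff c-o"),
    # straightforward matches between gaff and ff14SB types
    c("cd", "CX", 334.8, 1.5015, "gaff c3-cd"),
    c("nd", "CX", 334.7, 1.4560, "gaff c3-nd"),
    c("cf", "2C", 320.9, 1.5157, "gaff c3-cf"),
    c("ne", "C", 411.2, 1.3909, "gaff c-ne"),
    # parameters that treat atom CG2 as type cd
    c("cd", "CC", 419.8, 1.4278, "gaff cd-cd"),
    c("cd", "C*", 419.8, 1.4278, "gaff cd-cd"),
    # special cases
    c("nc", "cf", 525.4, 1.3172, "gaff nc-cd"),
    c("nf", "CX", 334.7, 1.4560, "gaff c3-nd")
  )
  data.frame(
    a1 = b[, 1L], a2 = b[, 2L],
    k_r = as.numeric(b[, 3L]), r_eq = as.numeric(b[, 4L]),
    source = b[, 5L], stringsAsFactors = FALSE
  )
}

.xfp_angle_table <- function() {
  a <- rbind(
    # direct matches for gaff parameters
    c("cc", "nc", "cd", 71.800, 105.490, "gaff cc-nc-cd"),
    c("cc", "c", "cc", 64.600, 115.840, "gaff cc-c-cc"),
    c("cc", "c", "nd", 67.800, 116.240, "gaff cc-c-nd"),
    c("cc", "c", "nf", 69.000, 112.220, "gaff cc-c-nf"),
    c("cc", "c", "o", 69.100, 123.930, "gaff cc-c-o"),
    c("cc", "cd", "ha", 48.500, 121.760, "gaff cc-cd-ha"),
    c("cd", "cd", "cc", 68.200, 114.190, "gaff cc-cd-cd"),
    c("cd", "cc", "nc", 72.200, 111.650, "gaff cd-cc-nc"),
    c("cd", "cd", "ha", 47.100, 121.070, "gaff cd-cd-ha"),
    c("cd", "cc", "ha", 48.500, 121.760, "gaff cd-cc-ha"),
    c("nc", "cd", "nd", 74.000, 115.830, "gaff nc-cd-nd"),
    c("nd", "c", "o", 73.900, 123.180, "gaff nd-c-o"),
    c("nf", "c", "o", 73.000, 125.810, "gaff nf-c-o"),
    c("c", "cc", "cd", 65.100, 121.350, "gaff c-cc-cd"),
    c("c", "cc", "nc", 66.200, 123.320, "gaff c-cc-nc"),
    c("c", "cc", "ha", 46.900, 116.640, "gaff c-cc-ha"),
    c("cf", "cf", "ne", 68.600, 120.790, "gaff cf-cf-ne"),
    c("cf", "cf", "nf", 68.600, 120.790, "gaff cf-cf-ne"),
    # straightforward matches between gaff and ff14SB types
    c("CX", "cd", "nd", 66.000, 120.950, "gaff c3-cd-nd"),
    c("CX", "cd", "nc", 66.500, 122.410, "gaff c3-cd-nc"),
    c("2C", "cf", "ne", 66.900, 120.680, "gaff c3-cf-ne"),
    c("2C", "cf", "cf", 63.400, 117.120, "gaff c3-cf-cf"),
    c("N", "CX", "cd", 63.000, 110.100, "PARM10 C-CX-N"),
    c("C", "CX", "nd", 63.000, 110.100, "PARM10 C-CX-N"),
    c("C", "CX", "nf", 63.000, 110.100, "PARM10 C-CX-N"),
    c("O", "C", "ne", 80.000, 122.900, "PARM10 N-C-O"),
    c("CX", "C", "ne", 70.000, 116.600, "PARM10 CX-C-N"),
    c("XC", "C", "ne", 70.000, 116.600, "PARM19 XC-C-N"),
    c("H1", "CX", "cd", 50.000, 109.500, "PARM10 C-CX-H1"),
    c("H1", "CX", "nd", 50.000, 109.500, "PARM10 H1-CX-N"),
    c("H1", "CX", "nf", 50.000, 109.500, "PARM10 H1-CX-N"),
    c("3C", "CX", "cd", 63.000, 111.100, "ff14SB C-CX-3C"),
    c("2C", "CX", "cd", 63.000, 111.100, "ff14SB C-CX-2C"),
    c("cf", "2C", "2C", 63.000, 111.100, "ff14SB C-2C-2C"),
    c("cf", "2C", "HC", 50.000, 109.500, "ff14SB C-2C-HC"),
    # parameters that treat atom CG2 as type cd
    c("cc", "cd", "CC", 68.200, 114.190, "gaff cc-cd-cd"),
    c("CC", "cd", "ha", 47.100, 121.070, "gaff cd-cd-ha"),
    c("cc", "cd", "C*", 68.200, 114.190, "gaff cc-cd-cd"),
    c("C*", "cd", "ha", 47.100, 121.070, "gaff cd-cd-ha"),
    # parameters that maintain ring behavior in Trp and His
    c("cd", "C*", "CB", 70.00, 128.60, "PARM10 CT-C*-CB"),
    c("cd", "C*", "CW", 70.00, 125.00, "PARM10 CT-C*-CW"),
    c("cd", "CC", "NA", 70.00, 120.00, "PARM10 CT-CC-NA"),
    c("cd", "CC", "CV", 70.00, 120.00, "PARM10 CT-CC-CV"),
    c("cd", "CC", "NB", 70.00, 120.00, "PARM10 CT-CC-NB"),
    c("cd", "CC", "CW", 70.00, 120.00, "PARM10 CT-CC-CW"),
    # special cases
    c("cd", "cd", "cd", 66.600, 120.020, "gaff ca-ca-ca"),
    c("cd", "nd", "CX", 66.700, 120.490, "gaff c-nd-cc"),
    c("cd", "nd", "c", 66.700, 120.490, "gaff c-nd-cc"),
    c("c", "nd", "CX", 66.700, 120.490, "gaff c-nd-cc"),
    c("cf", "nf", "c", 66.500, 120.830, "gaff c2-nf-ca"),
    c("cf", "nf", "CX", 66.500, 120.830, "gaff c2-nf-ca"),
    c("c", "nf", "CX", 66.500, 120.830, "gaff c2-nf-ca"),
    c("cc", "nc", "cf", 71.800, 105.490, "gaff cc-nc-cd"),
    c("nf", "cf", "nc", 70.200, 127.960, "gaff nf-cf-ne"),
    c("cf", "cf", "nc", 68.600, 120.790, "gaff cf-cf-ne"),
    c("C", "ne", "cf", 67.700, 118.530, "gaff c-ne-c2")
  )
  data.frame(
    a1 = a[, 1L], a2 = a[, 2L], a3 = a[, 3L],
    k_theta = as.numeric(a[, 4L]), theta_eq = as.numeric(a[, 5L]),
    source = a[, 6L], stringsAsFactors = FALSE
  )
}

# Torsions: rows sharing a `group` id are components of one logical
# multi-term torsion (AMBER continuation convention on write: negative
# periodicity for all but the last component).  `per` is stored positive.
.xfp_torsion_table <- function() {
  d <- rbind(
    # direct matches for gaff parameters
    c("X", "cc", "cd", "X", 4, 16.0, 180, 2, "gaff X-cc-cd-X", 1),
    c("X", "cc", "nc", "X", 2, 9.5, 180, 2, "gaff X-cc-nc-X", 2),
    c("X", "cc", "c", "X", 4, 11.5, 180, 2, "gaff X-cc-c-X", 3),
    c("X", "cd", "cd", "X", 4, 16.0, 180, 2, "gaff X-cd-cd-X", 4),
    c("X", "cd", "nc", "X", 2, 9.5, 180, 2, "gaff X-cd-nc-X", 5),
    c("X", "cd", "nd", "X", 2, 9.5, 180, 2, "gaff X-cd-nd-X", 6),
    c("X", "c", "nd", "X", 2, 8.0, 180, 2, "gaff X-c-nd-X", 7),
    c("X", "c", "nf", "X", 2, 0.4, 180, 2, "gaff X-c-nf-X", 8),
    c("X", "cf", "nf", "X", 2, 1.6, 180, 2, "gaff X-cf-nf-X", 9),
    c("X", "cf", "cf", "X", 4, 4.0, 180, 2, "gaff X-cf-cf-X", 10),
    # parameters that treat atom CG2 as type cd
    c("X", "cd", "CC", "X", 4, 16.0, 180, 2, "gaff X-cd-cd-X", 11),
    c("X", "cd", "C*", "X", 4, 16.0, 180, 2, "gaff X-cd-cd-X", 12),
    # straightforward matches between gaff and ff14SB types
    c("X", "C", "ne", "X", 2, 0.4, 180, 2, "gaff X-c-ne-X", 13),
    c("X", "CX", "cd", "X", 6, 0.0, 0, 3, "gaff X-c3-cd-X", 14),
    c("X", "CX", "nf", "X", 6, 0.0, 0, 3, "gaff X-c3-n2-X and X-c3-nf-X", 15),
    # special cases
    c("X", "CX", "nd", "X", 6, 0.0, 0, 3, "gaff X-c3-n2-X and X-c3-nf-X", 16),
    c("X", "2C", "cf", "X", 6, 0.0, 0, 3, "gaff X-c3-ca-X and X-c3-cc-X", 17),
    c("X", "cf", "nc", "X", 2, 9.5, 180, 2, "gaff X-cd-nc-X", 18),
    c("X", "cf", "ne", "X", 2, 8.3, 180, 2, "gaff X-c2-ne-X and X-c2-n2-X", 19),
    # using ff14SB parameters for sidechain torsions
    c("cd", "CX", "3C", "CT", 1, 0.112, 0, 4, "ff14SB C-CX-3C-CT", 20),
    c("cd", "CX", "3C", "CT", 1, 0.148, 0, 3, "component 2", 20),
    c("cd", "CX", "3C", "CT", 1, 0.289, 180, 2, "component 3", 20),
    c("cd", "CX", "3C", "CT", 1, 0.406, 180, 1, "component 4", 20),
    c("cd", "CX", "3C", "OH", 1, 0.156, 0, 4, "ff14SB C-CX-3C-OH", 21),
    c("cd", "CX", "3C", "OH", 1, 0.315, 0, 3, "component 2", 21),
    c("cd", "CX", "3C", "OH", 1, 0.119, 180, 2, "component 3", 21),
    c("cd", "CX", "3C", "OH", 1, 0.697, 180, 1, "component 4", 21),
    c("cd", "CX", "2C", "OH", 1, 0.129, 0, 4, "ff14SB C-CX-2C-OH", 22),
    c("cd", "CX", "2C", "OH", 1, 0.401, 0, 3, "component 2", 22),
    c("cd", "CX", "2C", "OH", 1, 0.218, 180, 2, "component 3", 22),
    c("cd", "CX", "2C", "OH", 1, 0.661, 180, 1, "component 4", 22),
    c("cf", "2C", "2C", "HC", 1, 0.160, 0, 3, "ff14SB CX-2C-2C-HC", 23),
    c("cf", "2C", "2C", "C", 1, 0.138, 0, 4, "ff14SB CX-2C-2C-C", 24),
    c("cf", "2C", "2C", "C", 1, 0.412, 180, 3, "component 2", 24),
    c("cf", "2C", "2C", "C", 1, 0.083, 0, 2, "component 3", 24),
    c("cf", "2C", "2C", "C", 1, 0.196, 180, 1, "component 4", 24),
    c("cf", "2C", "2C", "S", 1, 0.028, 0, 4, "ff14SB CX-2C-2C-S", 25),
    c("cf", "2C", "2C", "S", 1, 0.016, 0, 3, "component 2", 25),
    c("cf", "2C", "2C", "S", 1, 0.245, 0, 2, "component 3", 25),
    c("cf", "2C", "2C", "S", 1, 0.417, 0, 1, "component 4", 25)
  )
  data.frame(
    a1 = d[, 1L], a2 = d[, 2L], a3 = d[, 3L], a4 = d[, 4L],
    paths_divisor = as.integer(d[, 5L]),
    half_barrier = as.numeric(d[, 6L]),
    phase = as.numeric(d[, 7L]),
    periodicity = as.integer(d[, 8L]),
    source = d[, 9L],
    group = as.integer(d[, 10L]),
    stringsAsFactors = FALSE
  )
}

.xfp_improper_table <- function() {
  im <- rbind(
    c("X", "X", "c", "o", 10.5, 180, 2, "gaff X-X-c-o and PARM10 X-X-C-O"),
    c("X", "X", "cc", "ha", 1.1, 180, 2, "sp2 center"),
    c("X", "X", "cd", "ha", 1.1, 180, 2, "sp2 center"),
    c("c", "cd", "nd", "CX", 1.1, 180, 2, "sp2 center"),
    c("c", "cf", "nf", "CX", 1.1, 180, 2, "sp2 center"),
    c("cf", "ne", "cf", "2C", 1.1, 180, 2, "sp2 center"),
    c("nd", "nc", "cd", "CX", 1.1, 180, 2, "sp2 center"),
    c("nf", "nc", "cf", "cf", 1.1, 180, 2, "sp2 center"),
    c("cd", "cd", "cd", "cd", 1.1, 180, 2, "sp2 center"),
    c("nc", "c", "cc", "cd", 1.1, 180, 2, "sp2 center"),
    c("NA", "CV", "CC", "cd", 1.1, 180, 2, "PARM10 CT-CV-CC-NA"),
    c("NB", "CW", "CC", "cd", 1.1, 180, 2, "PARM10 CT-CW-CC-NB"),
    c("CW", "CB", "C*", "cd", 1.1, 180, 2, "PARM10 CB-CT-C*-CW")
  )
  data.frame(
    a1 = im[, 1L], a2 = im[, 2L], a3 = im[, 3L], a4 = im[, 4L],
    half_barrier = as.numeric(im[, 5L]),
    phase = as.numeric(im[, 6L]),
    periodicity = as.integer(im[, 7L]),
    source = im[, 8L], stringsAsFactors = FALSE
  )
}

.xfp_nonbonded_table <- function() {
  nb <- rbind(
    c("nd", 14.01, 0.530, 1.8240, 0.1700),
    c("nc", 14.01, 0.530, 1.8240, 0.1700),
    c("ne", 14.01, 0.530, 1.8240, 0.1700),
    c("nf", 14.01, 0.530, 1.8240, 0.1700),
    c("cc", 12.01, 0.360, 1.9080, 0.0860),
    c("cd", 12.01, 0.360, 1.9080, 0.0860),
    c("cf", 12.01, 0.360, 1.9080, 0.0860),
    c("c", 12.01, 0.616, 1.9080, 0.0860),
    c("ha", 1.008, 0.135, 1.4590, 0.0150),
    c("o", 16.00, 0.434, 1.6612, 0.2100)
  )
  data.frame(
    atom_type = nb[, 1L],
    mass = as.numeric(nb[, 2L]),
    polarizability = as.numeric(nb[, 3L]),
    r_star = as.numeric(nb[, 4L]),
    epsilon = as.numeric(nb[, 5L]),
    stringsAsFactors = FALSE
  )
}

# Cornell-family atom types assumed present in the loaded base force field
# (ff14SB/ff19SB); bonded terms may reference these without the document
# providing mass/nonbonded entries for them.
.xfp_base_ff_types <- c(
  "C", "CA", "CB", "CC", "CT", "CV", "CW", "CX", "XC", "C*", "2C", "3C",
  "N", "NA", "NB", "N2", "O", "OH", "S", "H", "H1", "HA", "HC", "HO"
)
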