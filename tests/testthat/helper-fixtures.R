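# Shared fixtures: hand-built mini structures, the standard mutated toy
# complex used across contact tests, and text-fixture writers.

# a bare Structure from parallel atom vectors
make_structure <- function(name, resname, chain, resseq, xyz,
                           element = NULL) {
  n <- length(name)
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  atoms <- data.frame(
    serial = seq_len(n), name = name, altloc = "",
    resname = resname, chain = chain, resseq = as.integer(resseq),
    icode = "", element = element, occupancy = 1, bfactor = 0,
    charge = NA_real_, mass = unname(masses[element]),
    stringsAsFactors = FALSE)
  methods::new("Structure", atoms = atoms, coords = xyz)
}

structure_as_traj <- function(st, frames = NULL) {
  n <- nrow(atoms(st))
  if (is.null(frames)) frames <- array(coords(st), c(n, 3, 1))
  methods::new("Trajectory", topology = st, frames = frames)
}

# toy complex with one mutated residue pair per contact kind; residues
# live mid-sheet so every kind can be planted
toy_complex <- function(n_strands = 5, residues_per_strand = 4,
                        torsion = 90, dC = 28) {
  dom_a <- buildToyDomain(n_strands, residues_per_strand, chain = "A",
                          mutations = c("10" = "GLU", "15" = "ASN",
                                        "8" = "LEU"))
  dom_b <- buildToyDomain(n_strands, residues_per_strand, chain = "B",
                          mutations = c("10" = "LYS", "15" = "ASN",
                                        "8" = "LEU"))
  assembleComplex(dom_a, dom_b, torsion = torsion, dC = dC)
}

standard_plants <- function(ratios = c(saltbridge = 0.65, hbond = 0.4,
                                       hydrophobic = 0.8, vdw = 0.5)) {
  res <- c(saltbridge = "10", hbond = "15", hydrophobic = "8",
           vdw = "18")
  lapply(names(ratios), function(k) {
    list(residue_a = paste0("A:", res[[k]]),
         residue_b = paste0("B:", res[[k]]),
         kind = k, target_ratio = unname(ratios[[k]]))
  })
}

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, b = 0, element = NULL, altloc = " ") {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resseq, x, y, z, occ, b,
          element)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
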