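# Programmatic PDB fixtures (fixed-column format, written at test time).

pdb_atom_line <- function(type = "ATOM", serial, name, alt = " ",
                          resname, chain = "A", resno, icode = " ",
                          x, y, z, occ = 1.00, bfac = 0.00, element = "") {
  if (element == "") element <- substr(gsub("[0-9']", "", name), 1L, 1L)
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_f, alt, resname, chain, resno, icode,
          x, y, z, occ, bfac, element)
}

# 5-residue poly-ALA chain (CA only plus one N to exercise selection),
# a water and a magnesium ion that must always be dropped
write_protein_pdb <- function(path) {
  lines <- character(0)
  s <- 1L
  for (i in 1:5) {
    lines <- c(lines,
               pdb_atom_line(serial = s, name = "N", resname = "ALA",
                             resno = i, x = i * 3.8 - 1, y = 0.5, z = 0),
               pdb_atom_line(serial = s + 1L, name = "CA", resname = "ALA",
                             resno = i, x = i * 3.8, y = 0, z = 0))
    s <- s + 2L
  }
  lines <- c(lines,
             pdb_atom_line(type = "HETATM", serial = s, name = "O",
                           resname = "HOH", chain = "B", resno = 101,
                           x = 30, y = 30, z = 30, element = "O"),
             pdb_atom_line(type = "HETATM", serial = s + 1L, name = "MG",
                           resname = "MG", chain = "B", resno = 102,
                           x = 40, y = 40, z = 40, element = "MG"),
             "END")
  writeLines(lines, path)
  path
}

# two-model file with distinct coordinates per model
write_multimodel_pdb <- function(path) {
  mk <- function(shift) {
    vapply(1:3, function(i)
      pdb_atom_line(serial = i, name = "CA", resname = "GLY", resno = i,
                    x = i * 3.8 + shift, y = 0, z = 0), "")
  }
  writeLines(c("MODEL     1", mk(0), "ENDMDL",
               "MODEL     2", mk(100), "ENDMDL", "END"), path)
  path
}

# altloc A/B pair on residue 2; B has the higher occupancy and must win
write_altloc_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(serial = 1, name = "CA", resname = "ALA", resno = 1,
                  x = 0, y = 0, z = 0),
    pdb_atom_line(serial = 2, name = "CA", alt = "A", resname = "SER",
                  resno = 2, x = 3.8, y = 0, z = 0, occ = 0.40),
    pdb_atom_line(serial = 3, name = "CA", alt = "B", resname = "SER",
                  resno = 2, x = 3.9, y = 0, z = 0, occ = 0.60),
    pdb_atom_line(serial = 4, name = "CA", resname = "ALA", resno = 3,
                  x = 7.6, y = 0, z = 0),
    "END")
  writeLines(lines, path)
  path
}

# short two-chain nucleic acid with phosphorus backbone atoms
write_dna_pdb <- function(path, n_per_chain = 4L) {
  lines <- character(0)
  s <- 1L
  for (ch in c("A", "B")) {
    for (i in seq_len(n_per_chain)) {
      lines <- c(lines,
                 pdb_atom_line(serial = s, name = "P", resname = "DG",
                               chain = ch, resno = i,
                               x = i * 6 + (ch == "B") * 2, y = (ch == "B") * 10,
                               z = i * 1.5, element = "P"),
                 pdb_atom_line(serial = s + 1L, name = "C1'", resname = "DG",
                               chain = ch, resno = i,
                               x = i * 6 + 1, y = 1, z = i * 1.5, element = "C"))
      s <- s + 2L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# filled triangle and related tiny complexes used in many places
fixture_filled_triangle <- function() simplicial_complex(list(1:3))
fixture_hollow_triangle <- function()
  simplicial_complex(list(c(1, 2), c(1, 3), c(2, 3)))
fixture_path3 <- function() simplicial_complex(list(c(1, 2), c(2, 3)))
fixture_square <- function()
  simplicial_complex(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
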