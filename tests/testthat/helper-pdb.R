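# Hand-rolled PDB ATOM line writer for reader tests (fixed-column format).

pdb_atom_line <- function(serial, name, resn, resno, x, y, z,
                          b = 0, occ = 1, chain = "A", alt = "",
                          element = substr(name, 1L, 1L)) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, substr(paste0(alt, " "), 1L, 1L), resn, chain,
          resno, " ", x, y, z, occ, b, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
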