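simple_model <- function() {
  node_model(list(
    list(id = "n1", type = "neurite",
         nodes = polyline(cbind(0:2, 0, 0), 0.5))),
    metadata = list(dataset = "X1"))
}

test_that("a 3-node constituent writes 3 ATOM, 2 CONECT, and END", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(simple_model(), path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "ATOM")), 3)
  expect_equal(sum(startsWith(lines, "CONECT")), 2)
  expect_equal(lines[length(lines)], "END")
  # fixed-column compliance: x field in 31-38, tempFactor in 61-66
  atom <- lines[startsWith(lines, "ATOM")][1]
  expect_equal(nchar(atom), 66)
  expect_equal(substr(atom, 31, 38), "   0.000")
  expect_equal(substr(atom, 61, 66), "  0.50")
  expect_equal(substr(atom, 18, 20), "NEU")
})

test_that("spine attachments become cross-constituent CONECT records", {
  m <- node_model(list(
    list(id = "n1", type = "neurite",
         nodes = polyline(cbind(0:6, 0, 0), 0.5)),
    list(id = "s1", type = "spine",
         nodes = polyline(cbind(c(4, 4, 4), c(0.5, 1, 1.5), 0), 0.2),
         attachment = list(parent_id = "n1", parent_node = 5))))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(m, path)
  lines <- readLines(path)
  # spine first node is serial 8; parent node 5 is serial 5
  expect_true("CONECT    8    5" %in% lines)
  m2 <- read_model_pdb(path)
  sp <- m2$constituents[[2]]
  expect_equal(sp$type, "spine")
  expect_equal(sp$attachment$parent_node, 5)
})

test_that("write -> read -> write is byte-identical", {
  path1 <- withr::local_tempfile(fileext = ".pdb")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  m <- random_model(101)
  write_model_pdb(m, path1)
  write_model_pdb(read_model_pdb(path1), path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("random models round-trip through the dialect", {
  for (seed in 1:100) {
    m <- random_model(seed)
    path <- tempfile(fileext = ".pdb")
    write_model_pdb(m, path)
    m2 <- read_model_pdb(path)
    expect_equal(length(m2$constituents), length(m$constituents))
    for (i in seq_along(m$constituents)) {
      a <- m$constituents[[i]]; b <- m2$constituents[[i]]
      expect_equal(b$type, a$type)
      expect_lt(max(abs(as.matrix(b$nodes[, c("x", "y", "z")]) -
                          as.matrix(a$nodes[, c("x", "y", "z")]))), 5.1e-4)
      expect_lt(max(abs(b$nodes$radius - a$nodes$radius)), 5.1e-3)
      expect_equal(is.null(b$attachment), is.null(a$attachment))
      if (!is.null(a$attachment)) {
        expect_equal(b$attachment$parent_node, a$attachment$parent_node)
      }
    }
    expect_equal(m2$metadata$dataset, m$metadata$dataset)
    expect_equal(m2$metadata$group, "schizophrenia")
    file.remove(path)
  }
})

test_that("malformed files are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(simple_model(), path)
  lines <- readLines(path)
  bad <- sub("NEU", "XXX", lines)
  writeLines(bad, path)
  expect_error(read_model_pdb(path), "XXX")

  writeLines(sub("   0.000", "  BROKEN", lines[startsWith(lines, "ATOM")])[1],
             path)
  expect_error(read_model_pdb(path), "malformed")
})

test_that("files without CONECT parse each chain/resSeq run as one constituent", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(node_model(list(
    list(id = "a", type = "neurite", nodes = polyline(cbind(0:3, 0, 0), 0.3)),
    list(id = "b", type = "soma", nodes = polyline(cbind(0:1, 5, 0), 1.2)))),
    path)
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "CONECT")], path)
  m <- read_model_pdb(path)
  expect_equal(length(m$constituents), 2)
  expect_equal(vapply(m$constituents, function(cc) cc$type, ""),
               c("neurite", "soma"))
  expect_equal(nrow(m$constituents[[1]]$nodes), 4)
})

test_that("coordinates overflowing the 8.3 field are rejected", {
  m <- node_model(list(list(id = "n", type = "neurite",
                            nodes = polyline(cbind(c(0, 20000), 0, 0), 0.5))))
  expect_error(write_model_pdb(m, tempfile()), "overflow")
})

test_that("validation reports unattached spines and duplicate nodes", {
  good <- random_model(7)
  expect_true(validate_model(good)$valid)

  bad <- node_model(list(
    list(id = "n1", type = "neurite", nodes = polyline(cbind(0:2, 0, 0), 0.5))))
  bad$constituents[[2]] <- list(id = "s1", type = "spine",
                                nodes = polyline(cbind(0:1, 1, 0), 0.1),
                                attachment = NULL)
  rep1 <- validate_model(bad)
  expect_false(rep1$valid)
  expect_true("unattached spine" %in% rep1$violations$issue)

  dup <- node_model(list(
    list(id = "n1", type = "neurite", nodes = polyline(cbind(0:3, 0, 0), 0.5))))
  dup$constituents[[1]]$nodes$x[2] <- dup$constituents[[1]]$nodes$x[1]
  dup$constituents[[1]]$nodes$y[2] <- dup$constituents[[1]]$nodes$y[1]
  dup$constituents[[1]]$nodes$z[2] <- dup$constituents[[1]]$nodes$z[1]
  rep2 <- validate_model(dup)
  expect_true(any(rep2$violations$issue == "duplicate consecutive nodes"))
  expect_true("n1" %in% rep2$violations$constituent_id)
})

test_that("SWC export links chains and spine parents", {
  m <- node_model(list(
    list(id = "n1", type = "neurite", nodes = polyline(cbind(0:4, 0, 0), 0.5)),
    list(id = "s1", type = "spine",
         nodes = polyline(cbind(c(2, 2), c(0.5, 1), 0), 0.2),
         attachment = list(parent_id = "n1", parent_node = 3))))
  path <- withr::local_tempfile(fileext = ".swc")
  write_model_swc(m, path)
  swc <- utils::read.table(path, comment.char = "#")
  names(swc) <- c("id", "type", "x", "y", "z", "radius", "parent")
  expect_equal(nrow(swc), 7)
  expect_equal(swc$parent[1], -1)
  expect_equal(swc$parent[2:5], 1:4)
  expect_equal(swc$type[6], 5)    # spine code
  expect_equal(swc$parent[6], 3)  # attached to parent node serial 3
})
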