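# QR symbol constants (ISO/IEC 18004): byte-mode data capacities for all
# versions and error-correction levels, Reed-Solomon block structures for
# level L (the level this protocol prints at), and alignment pattern centre
# coordinates. The block table is cross-checked in the test suite against an
# independent geometry computation (non-function module count of the built
# symbol matrix) and against the capacity table via the mode/length header
# arithmetic.

# byte-mode capacity in bytes; rows = versions 1..40, columns L, M, Q, H
QR_CAPACITY <- matrix(c(
    17,   14,   11,    7,
    32,   26,   20,   14,
    53,   42,   32,   24,
    78,   62,   46,   34,
   106,   84,   60,   44,
   134,  106,   74,   58,
   154,  122,   86,   64,
   192,  152,  108,   84,
   230,  180,  130,   98,
   271,  213,  151,  119,
   321,  251,  177,  137,
   367,  287,  203,  155,
   425,  331,  241,  177,
   458,  362,  258,  194,
   520,  412,  292,  220,
   586,  450,  322,  250,
   644,  504,  364,  280,
   718,  560,  394,  310,
   792,  624,  442,  338,
   858,  666,  482,  382,
   929,  711,  509,  403,
  1003,  779,  565,  439,
  1091,  857,  611,  461,
  1171,  911,  661,  511,
  1273,  997,  715,  535,
  1367, 1059,  751,  593,
  1465, 1125,  805,  625,
  1528, 1190,  868,  658,
  1628, 1264,  908,  698,
  1732, 1370,  982,  742,
  1840, 1452, 1030,  790,
  1952, 1538, 1112,  842,
  2068, 1628, 1168,  898,
  2188, 1722, 1228,  958,
  2303, 1809, 1283,  983,
  2431, 1911, 1351, 1051,
  2563, 1989, 1423, 1093,
  2699, 2099, 1499, 1139,
  2809, 2213, 1579, 1219,
  2953, 2331, 1663, 1273
), ncol = 4, byrow = TRUE, dimnames = list(NULL, c("L", "M", "Q", "H")))

# level-L Reed-Solomon structure per version:
# g1n blocks of g1d data codewords, then g2n blocks of g2d, each block with
# ec error-correction codewords
QR_BLOCKS_L <- matrix(c(
  # g1n  g1d g2n  g2d  ec
     1,   19,  0,   0,  7,
     1,   34,  0,   0, 10,
     1,   55,  0,   0, 15,
     1,   80,  0,   0, 20,
     1,  108,  0,   0, 26,
     2,   68,  0,   0, 18,
     2,   78,  0,   0, 20,
     2,   97,  0,   0, 24,
     2,  116,  0,   0, 30,
     2,   68,  2,  69, 18,
     4,   81,  0,   0, 20,
     2,   92,  2,  93, 24,
     4,  107,  0,   0, 26,
     3,  115,  1, 116, 30,
     5,   87,  1,  88, 22,
     5,   98,  1,  99, 24,
     1,  107,  5, 108, 28,
     5,  120,  1, 121, 30,
     3,  113,  4, 114, 28,
     3,  107,  5, 108, 28,
     4,  116,  4, 117, 28,
     2,  111,  7, 112, 28,
     4,  121,  5, 122, 30,
     6,  117,  4, 118, 30,
     8,  106,  4, 107, 26,
    10,  114,  2, 115, 28,
     8,  122,  4, 123, 30,
     3,  117, 10, 118, 30,
     7,  116,  7, 117, 30,
     5,  115, 10, 116, 30,
    13,  115,  3, 116, 30,
    17,  115,  0,   0, 30,
    17,  115,  1, 116, 30,
    13,  115,  6, 116, 30,
    12,  121,  7, 122, 30,
     6,  121, 14, 122, 30,
    17,  122,  4, 123, 30,
     4,  122, 18, 123, 30,
    20,  117,  4, 118, 30,
    19,  118,  6, 119, 30
), ncol = 5, byrow = TRUE,
  dimnames = list(NULL, c("g1n", "g1d", "g2n", "g2d", "ec")))

# alignment pattern centre coordinates (0-indexed), one vector per version
QR_ALIGN <- list(
  integer(0),
  c(6, 18), c(6, 22), c(6, 26), c(6, 30), c(6, 34),
  c(6, 22, 38), c(6, 24, 42), c(6, 26, 46), c(6, 28, 50),
  c(6, 30, 54), c(6, 32, 58), c(6, 34, 62),
  c(6, 26, 46, 66), c(6, 26, 48, 70), c(6, 26, 50, 74),
  c(6, 30, 54, 78), c(6, 30, 56, 82), c(6, 30, 58, 86), c(6, 34, 62, 90),
  c(6, 28, 50, 72, 94), c(6, 26, 50, 74, 98), c(6, 30, 54, 78, 102),
  c(6, 28, 54, 80, 106), c(6, 32, 58, 84, 110), c(6, 30, 58, 86, 114),
  c(6, 34, 62, 90, 118),
  c(6, 26, 50, 74, 98, 122), c(6, 30, 54, 78, 102, 126),
  c(6, 26, 52, 78, 104, 130), c(6, 30, 56, 82, 108, 134),
  c(6, 34, 60, 86, 112, 138), c(6, 30, 58, 86, 114, 142),
  c(6, 34, 62, 90, 118, 146),
  c(6, 30, 54, 78, 102, 126, 150), c(6, 24, 50, 76, 102, 128, 154),
  c(6, 28, 54, 80, 106, 132, 158), c(6, 32, 58, 84, 110, 136, 162),
  c(6, 26, 54, 82, 110, 138, 166), c(6, 30, 58, 86, 114, 142, 170)
)

# number of data codewords for (version, level) implied by the byte capacity
# and the byte-mode header (4-bit mode + 8/16-bit length + <=4-bit terminator)
qr_data_codewords <- function(version, ec_level) {
  cap <- QR_CAPACITY[version, ec_level]
  len_bits <- if (version <= 9L) 8L else 16L
  ceiling((8L * cap + 4L + len_bits) / 8L)
}
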