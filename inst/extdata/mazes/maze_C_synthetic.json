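{
  "vertices": [
    {
      "id": 1,
      "degree": 3
    },
    {
      "id": 2,
      "degree": 3
    },
    {
      "id": 3,
      "degree": 1
    },
    {
      "id": 4,
      "degree": 1
    },
    {
      "id": 5,
      "degree": 1
    },
    {
      "id": 6,
      "degree": 1
    },
    {
      "id": 7,
      "degree": 3
    },
    {
      "id": 8,
      "degree": 3
    },
    {
      "id": 9,
      "degree": 1
    },
    {
      "id": 10,
      "degree": 1
    },
    {
      "id": 11,
      "degree": 3
    },
    {
      "id": 12,
      "degree": 1
    },
    {
      "id": 13,
      "degree": 1
    },
    {
      "id": 14,
      "degree": 4
    },
    {
      "id": 15,
      "degree": 3
    },
    {
      "id": 16,
      "degree": 4
    },
    {
      "id": 17,
      "degree": 1
    },
    {
      "id": 18,
      "degree": 1
    },
    {
      "id": 19,
      "degree": 1
    },
    {
      "id": 20,
      "degree": 3
    },
    {
      "id": 21,
      "degree": 1
    },
    {
      "id": 22,
      "degree": 1
    },
    {
      "id": 23,
      "degree": 3
    },
    {
      "id": 24,
      "degree": 1
    },
    {
      "id": 25,
      "degree": 1
    },
    {
      "id": 26,
      "degree": 1
    },
    {
      "id": 27,
      "degree": 3
    },
    {
      "id": 28,
      "degree": 3
    }
  ],
  "edges": [
    [1, 2],
    [1, 7],
    [1, 5],
    [2, 3],
    [2, 6],
    [4, 8],
    [7, 8],
    [7, 14],
    [8, 9],
    [10, 11],
    [11, 12],
    [11, 16],
    [13, 14],
    [14, 15],
    [14, 17],
    [15, 16],
    [15, 20],
    [16, 23],
    [16, 18],
    [19, 20],
    [20, 21],
    [22, 23],
    [23, 28],
    [24, 27],
    [25, 28],
    [26, 27],
    [27, 28]
  ],
  "start": 26,
  "egg": 3
}
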