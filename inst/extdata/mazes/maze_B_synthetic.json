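{
  "vertices": [
    {
      "id": 1,
      "degree": 3
    },
    {
      "id": 2,
      "degree": 1
    },
    {
      "id": 3,
      "degree": 1
    },
    {
      "id": 4,
      "degree": 3
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
      "degree": 1
    },
    {
      "id": 9,
      "degree": 3
    },
    {
      "id": 10,
      "degree": 1
    },
    {
      "id": 11,
      "degree": 1
    },
    {
      "id": 12,
      "degree": 3
    }
  ],
  "edges": [
    [1, 2],
    [1, 4],
    [1, 3],
    [4, 5],
    [4, 7],
    [6, 7],
    [7, 9],
    [8, 9],
    [9, 12],
    [10, 12],
    [11, 12]
  ],
  "start": 11,
  "egg": 2
}
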