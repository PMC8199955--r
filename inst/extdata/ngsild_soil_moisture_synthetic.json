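{
  "id": "urn:ngsi-ld:SoilMoistureSensor:synthetic-001",
  "type": "SoilMoistureSensor",
  "location": {
    "type": "GeoProperty",
    "value": { "type": "Point", "coordinates": [-1.2165, 37.9871] }
  },
  "soilMoisture10cm": {
    "type": "Property",
    "value": 31.4,
    "observedAt": "2021-03-01T10:00:00Z",
    "location": {
      "type": "GeoProperty",
      "value": { "type": "Point", "coordinates": [-1.2165, 37.9871, -10] }
    }
  },
  "soilMoisture20cm": {
    "type": "Property",
    "value": 33.8,
    "observedAt": "2021-03-01T10:00:00Z",
    "location": {
      "type": "GeoProperty",
      "value": { "type": "Point", "coordinates": [-1.2165, 37.9871, -20] }
    }
  },
  "soilMoisture30cm": {
    "type": "Property",
    "value": 35.1,
    "observedAt": "2021-03-01T10:00:00Z",
    "location": {
      "type": "GeoProperty",
      "value": { "type": "Point", "coordinates": [-1.2165, 37.9871, -30] }
    }
  },
  "soilMoisture40cm": {
    "type": "Property",
    "value": 36.0,
    "observedAt": "2021-03-01T10:00:00Z",
    "location": {
      "type": "GeoProperty",
      "value": { "type": "Point", "coordinates": [-1.2165, 37.9871, -40] }
    }
  },
  "soilMoisture50cm": {
    "type": "Property",
    "value": 36.6,
    "observedAt": "2021-03-01T10:00:00Z",
    "location": {
      "type": "GeoProperty",
      "value": { "type": "Point", "coordinates": [-1.2165, 37.9871, -50] }
    }
  },
  "soilMoisture60cm": {
    "type": "Property",
    "value": 37.2,
    "observedAt": "2021-03-01T10:00:00Z",
    "location": {
      "type": "GeoProperty",
      "value": { "type": "Point", "coordinates": [-1.2165, 37.9871, -60] }
    }
  },
  "batteryLevel": {
    "type": "Property",
    "value": 0.87,
    "observedAt": "2021-03-01T10:00:00Z"
  }
}
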